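test_that("zero-noise cohorts reproduce the theoretical factor exactly", {
  cfg <- simulation_config(c(cyclobenzaprine = 19.6, methadone = 4.8),
                           n_per_drug = 10, sigma_lp = 0, sigma_f = 0,
                           seed = 101L)
  cohort <- simulate_cohort(cfg)
  obs <- cohort$observations
  expect_equal(nrow(obs), 20L)
  for (d in names(cfg$lp_median)) {
    f <- obs$p_conc[obs$drug == d] / obs$am_conc[obs$drug == d]
    expect_equal(f, rep(ft_exact(cfg$lp_median[[d]]), 10))
  }
  # and recovery from the per-case L/P draws is exact
  rec <- recover_ft(cohort)
  expect_equal(rec$abs_error, c(0, 0))
})

test_that("cohorts are reproducible from (config, seed) and vary across seeds", {
  lp <- c(doxepin = 19.4, fentanyl = 5.9)
  c1 <- simulate_cohort(simulation_config(lp, 25, seed = 42L))
  c2 <- simulate_cohort(simulation_config(lp, 25, seed = 42L))
  c3 <- simulate_cohort(simulation_config(lp, 25, seed = 43L))
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$truth, c2$truth)
  expect_false(isTRUE(all.equal(c1$observations$p_conc,
                                c3$observations$p_conc)))
})

test_that("the sample median of P/AM tracks the generating factor", {
  cfg <- simulation_config(c(cyclobenzaprine = 19.6), n_per_drug = 500,
                           sigma_lp = 0, sigma_f = 0.1, seed = 7L)
  obs <- simulate_cohort(cfg)$observations
  med <- stats::median(obs$p_conc / obs$am_conc)
  # lognormal noise has median 1, so the cohort median should sit near
  # the exact factor 2.55
  expect_lt(abs(med - ft_exact(19.6)) / ft_exact(19.6), 0.05)
})

test_that("median-based recovery returns the factor within 0.1 across the panel", {
  ref <- load_reference_table()
  comp <- ref[ref$ft_source == "computed", ]
  cfg <- simulation_config(stats::setNames(comp$lp_median, comp$drug),
                           n_per_drug = 200, sigma_lp = 0.2, sigma_f = 0.1,
                           seed = 20161216L)
  rec <- recover_ft(simulate_cohort(cfg))
  expect_equal(nrow(rec), 43L)
  expect_true(all(rec$abs_error < 0.1))
})

test_that("recovery error shrinks with cohort size", {
  lp <- stats::setNames(c(1.1, 4.8, 11.2, 19.6, 76.0),
                        c("a", "b", "c", "d", "e"))
  err <- vapply(c(10, 100, 1000), function(n) {
    cfg <- simulation_config(lp, n_per_drug = n, sigma_lp = 0.2,
                             sigma_f = 0.1, seed = 99L)
    mean(recover_ft(simulate_cohort(cfg))$abs_error)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("a singleton drug group recovers the median of one case", {
  cfg <- simulation_config(c(methadone = 4.8), n_per_drug = 1,
                           sigma_lp = 0.3, seed = 3L)
  cohort <- simulate_cohort(cfg)
  rec <- recover_ft(cohort)
  expect_equal(rec$lp_est, cohort$truth$lp_case)
  expect_equal(rec$ft_est, ft_exact(cohort$truth$lp_case))
})

test_that("zero-noise cohorts validate to an identity regression at full precision", {
  cfg <- simulation_config(c(a = 1.1, b = 4.8, c = 19.6, d = 76.0),
                           n_per_drug = 5, sigma_lp = 0, sigma_f = 0,
                           seed = 17L)
  cohort <- simulate_cohort(cfg)
  v <- run_validation(cohort$observations, cohort_reference(cohort),
                      precision = "full")
  expect_equal(v$regression$slope, 1)
  expect_equal(v$regression$intercept, 0)
  expect_equal(v$regression$r_squared, 1)
})

test_that("configs are validated and cohorts round-trip through CSV", {
  expect_error(simulation_config(c(1, 2), 5), "named")
  expect_error(simulation_config(c(a = -1), 5), "positive")
  expect_error(simulation_config(c(a = 1), 0), "n_per_drug")
  expect_error(simulation_config(c(a = 1), 5, sigma_lp = -0.1), "non-negative")
  expect_error(simulation_config(c(a = 1), 5, am_range = c(5, 1)), "bounds")
  expect_error(simulation_config(c(a = 1, A = 2), 5), "duplicate")

  cohort <- simulate_cohort(simulation_config(c(quetiapine = 11.2), 8,
                                              seed = 55L))
  cases_path <- withr::local_tempfile(fileext = ".csv")
  truth_path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, cases_path, truth_path)
  reloaded <- load_case_table(cases_path)
  expect_equal(reloaded, cohort$observations)
  truth <- utils::read.csv(truth_path)
  expect_equal(unique(truth$seed), 55L)
  expect_equal(nrow(truth), 8L)
})
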