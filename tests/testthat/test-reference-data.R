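test_that("the shipped reference table loads with the published content", {
  ref <- load_reference_table()
  expect_s3_class(ref, "drug_reference")
  expect_equal(nrow(ref), 44L)
  expect_equal(sum(ref$n_cases, na.rm = TRUE), 867)

  cyc <- ref[ref$drug == "cyclobenzaprine", ]
  expect_equal(cyc$n_cases, 13)
  expect_equal(cyc$lp_median, 19.6)
  expect_equal(cyc$ft_published, 2.5)

  eth <- ref[ref$drug == "ethanol", ]
  expect_equal(eth$ft_source, "literature")
  expect_equal(eth$ft_published, 1.0)
  expect_true(is.na(eth$lp_median))
  expect_equal(sum(ref$ft_source == "literature"), 1L)

  expect_true(all(ref$ft_published >= 0.97 & ref$ft_published <= 4.8))
})

test_that("the shipped case table loads in printed order with timing covariates", {
  cases <- load_case_table()
  expect_s3_class(cases, "pmr_cases")
  expect_equal(nrow(cases), 13L)
  expect_equal(table(cases$drug)[["methamphetamine"]], 3L)
  expect_equal(cases$drug[1:3], c("ethanol", "ethanol", "gabapentin"))

  meth <- cases[cases$drug == "methadone", ]
  expect_equal(meth$p_conc, 0.56)
  expect_equal(meth$am_conc, 0.39)
  expect_equal(meth$t1_minutes, 18)
  expect_equal(meth$t2_hours, 6.7)

  fen <- cases[cases$drug == "fentanyl", ]
  expect_equal(fen$p_conc, 0.0016)
  expect_equal(fen$am_conc, 0.0014)

  # autopsies within the 48-hour window
  expect_equal(min(cases$t2_hours), 5.2)
  expect_equal(max(cases$t2_hours), 42)
})

test_that("loading validates structure and rejects malformed input", {
  empty <- write_lines_tmp("drug,n,lp_median,ft,ft_source")
  expect_equal(nrow(load_reference_table(empty)), 0L)

  dup <- write_lines_tmp(c("drug,n,lp_median,ft,ft_source",
                           "methadone,94,4.8,1.4,computed",
                           "Methadone,94,4.8,1.4,computed"))
  expect_error(load_reference_table(dup), "duplicate")

  badnum <- write_lines_tmp(c("drug,n,lp_median,ft,ft_source",
                              "methadone,94,four,1.4,computed"))
  expect_error(load_reference_table(badnum), "row\\(s\\): 1")

  nonpos <- write_lines_tmp(c("drug,n,lp_median,ft,ft_source",
                              "methadone,94,-4.8,1.4,computed"))
  expect_error(load_reference_table(nonpos), "positive")

  badhdr <- write_lines_tmp(c("name,n,lp,ft,src", "methadone,94,4.8,1.4,x"))
  expect_error(load_reference_table(badhdr), "header")

  # a computed entry must carry its L/P median; literature must not
  nolp <- write_lines_tmp(c("drug,n,lp_median,ft,ft_source",
                            "methadone,94,,1.4,computed"))
  expect_error(load_reference_table(nolp), "lp_median")
  litlp <- write_lines_tmp(c("drug,n,lp_median,ft,ft_source",
                             "ethanol,,1.0,1.0,literature"))
  expect_error(load_reference_table(litlp), "literature")

  badcase <- write_lines_tmp(c("drug,p,am,f,ft,t1_min,t2_h",
                               "methadone,0.56,0,1.4,1.4,18,6.7"))
  expect_error(load_case_table(badcase), "positive")
})

test_that("write_table round-trips both schemas through their loaders", {
  ref <- load_reference_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(ref, path)
  expect_equal(load_reference_table(path), ref)

  cases <- load_case_table()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_table(cases, path2)
  expect_equal(load_case_table(path2), cases)

  # single entry: header plus one data row
  one <- ref[ref$drug == "methadone", ]
  class(one) <- class(ref)
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_table(one, path3)
  expect_length(readLines(path3), 2L)

  dup <- rbind(ref, ref[1, ])
  class(dup) <- class(ref)
  expect_error(write_table(dup, path3), "duplicate")
})

test_that("fixture validation passes on the shipped table and catches tampering", {
  ref <- load_reference_table()
  report <- validate_reference_fixture(ref)
  expect_true(all(report$pass))
  expect_equal(report$observed[report$check == "ft_recomputation"], 43)
  expect_length(attr(report, "disagreements"), 0L)

  tampered <- ref
  tampered$ft_published[tampered$drug == "sertraline"] <- 4.9
  bad <- validate_reference_fixture(tampered)
  expect_false(bad$pass[bad$check == "ft_recomputation"])
  expect_equal(attr(bad, "disagreements"), "sertraline")
})
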