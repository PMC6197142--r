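#' Configure a synthetic paired-case cohort
#'
#' Defines the generating process for synthetic antemortem/postmortem case
#' pairs with the statistical structure the redistribution-factor model
#' assumes. For each case of a drug with true median L/P ratio `R`:
#' the antemortem concentration `AM` is drawn log-uniformly within
#' `am_range`; the case's true factor is `F = Ft(R) * exp(eps)` with
#' `eps ~ Normal(0, sigma_f^2)` (multiplicative lognormal noise, median 1);
#' the postmortem peripheral concentration is `P = F * AM`; and a per-case
#' L/P ratio is drawn as `R * exp(eta)`, `eta ~ Normal(0, sigma_lp^2)`.
#' Postmortem delay is generated uniformly within `delay_range` as an inert
#' covariate (the model treats delays within its 48-hour window as
#' exchangeable).
#'
#' Lognormal multiplicative noise is used because concentrations and ratios
#' are positive and right-skewed; its median of 1 keeps the drug-level
#' median L/P and median `P/AM` centred on the generating truth.
#'
#' @param lp_median named numeric vector: true median L/P ratio per drug
#'   (names are drug identifiers), all > 0.
#' @param n_per_drug number of cases per drug (single value or one per
#'   drug), >= 1.
#' @param sigma_lp lognormal scale of per-case L/P scatter (log scale, >= 0).
#' @param sigma_f lognormal scale of case-level redistribution noise around
#'   the theoretical factor (log scale, >= 0).
#' @param am_range length-2 positive bounds for the log-uniform antemortem
#'   concentration draw (mg/L).
#' @param delay_range length-2 positive bounds (hours) for the postmortem
#'   delay draw.
#' @param seed integer random seed; recorded in every cohort.
#' @return a `pmr_sim_config` list.
#' @examples
#' cfg <- simulation_config(c(cyclobenzaprine = 19.6), n_per_drug = 50)
#' @export
simulation_config <- function(lp_median, n_per_drug,
                              sigma_lp = 0.2, sigma_f = 0.1,
                              am_range = c(0.01, 10),
                              delay_range = c(5, 48),
                              seed = 20161216L) {
  if (!is.numeric(lp_median) || length(lp_median) == 0L ||
      is.null(names(lp_median)) || any(!nzchar(names(lp_median)))) {
    stop("lp_median must be a non-empty named numeric vector", call. = FALSE)
  }
  check_positive_numeric(unname(lp_median), "lp_median")
  if (any(duplicated(tolower(names(lp_median))))) {
    stop("duplicate drug names in lp_median", call. = FALSE)
  }
  n_per_drug <- as.integer(n_per_drug)
  if (length(n_per_drug) == 1L) {
    n_per_drug <- rep(n_per_drug, length(lp_median))
  }
  if (length(n_per_drug) != length(lp_median) || any(n_per_drug < 1L)) {
    stop("n_per_drug must be >= 1, length 1 or one per drug", call. = FALSE)
  }
  for (s in c(sigma_lp, sigma_f)) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0) {
      stop("noise scales must be single non-negative numbers", call. = FALSE)
    }
  }
  for (b in list(am_range, delay_range)) {
    if (length(b) != 2L || anyNA(b) || any(b <= 0) || b[1] > b[2]) {
      stop("ranges must be ordered positive length-2 bounds", call. = FALSE)
    }
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(lp_median = lp_median, n_per_drug = n_per_drug,
                 sigma_lp = sigma_lp, sigma_f = sigma_f,
                 am_range = am_range, delay_range = delay_range,
                 seed = seed),
            class = "pmr_sim_config")
}

#' Simulate a synthetic paired-case cohort
#'
#' Draws a cohort from the generating process described in
#' [simulation_config()]. The same configuration (including its seed)
#' always reproduces the cohort exactly.
#'
#' @param config a `pmr_sim_config` from [simulation_config()].
#' @return a `pmr_cohort` list: `observations` (a `pmr_cases` data frame
#'   in the paired-case schema, with displayed factors filled in),
#'   `truth` (per-case true factor, per-case L/P draw, per-drug true median
#'   ratio and exact theoretical factor), and `config`.
#' @examples
#' cfg <- simulation_config(c(methadone = 4.8), n_per_drug = 5, seed = 1L)
#' cohort <- simulate_cohort(cfg)
#' cohort$observations
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "pmr_sim_config")) {
    stop("config must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  drugs <- names(config$lp_median)
  per_drug <- lapply(seq_along(drugs), function(i) {
    n <- config$n_per_drug[i]
    r_true <- config$lp_median[[i]]
    ft_true <- ft_exact(r_true)
    am <- exp(stats::runif(n, log(config$am_range[1]),
                           log(config$am_range[2])))
    f_true <- ft_true * exp(stats::rnorm(n, 0, config$sigma_f))
    p <- f_true * am
    lp_case <- r_true * exp(stats::rnorm(n, 0, config$sigma_lp))
    t2 <- stats::runif(n, config$delay_range[1], config$delay_range[2])
    list(
      obs = data.frame(
        drug = drugs[i], p_conc = p, am_conc = am,
        f_printed = format_f(p / am),
        ft_printed = format_ft(rep(ft_true, n)),
        t1_minutes = 0, t2_hours = t2,
        stringsAsFactors = FALSE
      ),
      truth = data.frame(
        drug = drugs[i], lp_true_median = r_true, ft_true = ft_true,
        f_case_true = f_true, lp_case = lp_case,
        stringsAsFactors = FALSE
      )
    )
  })
  observations <- do.call(rbind, lapply(per_drug, `[[`, "obs"))
  truth <- do.call(rbind, lapply(per_drug, `[[`, "truth"))
  rownames(observations) <- rownames(truth) <- NULL
  class(observations) <- c("pmr_cases", "data.frame")
  structure(list(observations = observations, truth = truth,
                 config = config),
            class = "pmr_cohort")
}

#' Recover per-drug theoretical factors from a synthetic cohort
#'
#' Estimates each drug's theoretical redistribution factor the way the
#' reference table was built: the median of the per-case L/P draws is fed
#' through the factor model, and the estimate is compared with the
#' generating truth.
#'
#' @param cohort a `pmr_cohort` from [simulate_cohort()].
#' @return data frame, one row per drug: `drug`, `n_cases`, `lp_true`,
#'   `ft_true`, `lp_est` (sample median of per-case draws), `ft_est`,
#'   `abs_error`.
#' @examples
#' cfg <- simulation_config(c(doxepin = 19.4), n_per_drug = 200, seed = 7L)
#' recover_ft(simulate_cohort(cfg))
#' @export
recover_ft <- function(cohort) {
  if (!inherits(cohort, "pmr_cohort")) {
    stop("cohort must come from simulate_cohort()", call. = FALSE)
  }
  truth <- cohort$truth
  if (nrow(truth) == 0L) {
    stop("insufficient data: empty cohort", call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(truth)), truth$drug)
  rows <- lapply(split_idx, function(idx) {
    lp_est <- stats::median(truth$lp_case[idx])
    ft_est <- ft_exact(lp_est)
    data.frame(
      drug = truth$drug[idx[1]],
      n_cases = length(idx),
      lp_true = truth$lp_true_median[idx[1]],
      ft_true = truth$ft_true[idx[1]],
      lp_est = lp_est,
      ft_est = ft_est,
      abs_error = abs(ft_est - truth$ft_true[idx[1]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a reference table from a cohort's generating truth
#'
#' Packages the simulated drugs' true median L/P ratios as a
#' `drug_reference` table (with the displayed theoretical factor each ratio
#' implies), so a synthetic cohort can be pushed through [compare_cases()]
#' and [run_validation()] exactly like real data.
#'
#' @param cohort a `pmr_cohort`.
#' @return a `drug_reference` data frame, one row per simulated drug.
#' @export
cohort_reference <- function(cohort) {
  stopifnot(inherits(cohort, "pmr_cohort"))
  lp <- cohort$config$lp_median
  out <- data.frame(
    drug = names(lp),
    n_cases = cohort$config$n_per_drug,
    lp_median = unname(lp),
    ft_published = format_ft(ft_exact(unname(lp))),
    ft_source = "computed",
    stringsAsFactors = FALSE
  )
  class(out) <- c("drug_reference", "data.frame")
  out
}

#' Write a cohort to CSV files
#'
#' Emits the observations in the paired-case schema (loadable with
#' [load_case_table()]) and the generating truth as a sidecar table, with
#' the seed recorded in the truth file's `seed` column.
#'
#' @param cohort a `pmr_cohort`.
#' @param cases_path destination for the observations CSV.
#' @param truth_path destination for the truth CSV.
#' @return invisibly, `c(cases_path, truth_path)`.
#' @export
write_cohort <- function(cohort, cases_path, truth_path) {
  stopifnot(inherits(cohort, "pmr_cohort"))
  write_table(cohort$observations, cases_path)
  truth <- cohort$truth
  truth$seed <- cohort$config$seed
  write_pmr_csv(truth, truth_path)
  invisible(c(cases_path, truth_path))
}
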