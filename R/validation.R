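#' Simple ordinary least squares fit with an F test
#'
#' Fits `y = intercept + slope * x` by least squares (via [stats::lm()]) and
#' summarizes the fit the way the model validation reports it: slope,
#' intercept, coefficient of determination, the overall F statistic on
#' (1, n - 2) degrees of freedom, and its upper-tail p-value.
#'
#' @param x predictor values (numeric, length >= 3, not constant).
#' @param y response values, same length.
#' @return an object of class `pmr_ols`: a list with elements `slope`,
#'   `intercept`, `r_squared`, `f_statistic`, `df` (c(1, n - 2)), `p_value`,
#'   `n`, and `fitted`.
#' @examples
#' fit <- ols_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' fit$slope
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  n <- length(x)
  if (n < 3L) {
    stop("insufficient data: at least 3 points are required", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate design: x is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  fstat <- if (r2 < 1) r2 * (n - 2) / (1 - r2) else Inf
  structure(list(
    slope = unname(co[["x"]]),
    intercept = unname(co[["(Intercept)"]]),
    r_squared = r2,
    f_statistic = fstat,
    df = c(1L, n - 2L),
    p_value = stats::pf(fstat, 1, n - 2, lower.tail = FALSE),
    n = n,
    fitted = unname(stats::fitted(fit))
  ), class = "pmr_ols")
}

#' @export
print.pmr_ols <- function(x, ...) {
  cat(sprintf("Least-squares fit (n = %d)\n", x$n))
  cat(sprintf("  y = %.4fx + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, F(%d,%d) = %.3f, p = %.3g\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Compare determined and theoretical redistribution factors case by case
#'
#' For each paired case, recomputes the determined factor `F = P / AM` from
#' the concentrations, looks up the drug's theoretical factor in the
#' reference table (falling back to the case record's own reported value if
#' the drug is absent), and tabulates both at display precision together
#' with their absolute and relative differences. Also summarizes the
#' postmortem-delay covariate (mean, sample SD, median, min, max).
#'
#' @param cases a `pmr_cases` data frame (see [load_case_table()]).
#' @param reference a `drug_reference` data frame (see
#'   [load_reference_table()]); matching is case-insensitive.
#' @return an object of class `pmr_case_comparison`: a list with `cases`
#'   (one row per input case: `drug`, `p_conc`, `am_conc`, `f_exact`,
#'   `f_displayed`, `f_printed`, `ft_displayed`, `abs_diff`, `rel_diff`,
#'   `t2_hours`) and `delay_summary`.
#' @examples
#' cmp <- compare_cases(load_case_table(), load_reference_table())
#' cmp$delay_summary
#' @export
compare_cases <- function(cases, reference) {
  stopifnot(inherits(cases, "pmr_cases"), inherits(reference, "drug_reference"))
  if (nrow(cases) == 0L) {
    stop("insufficient data: no case records", call. = FALSE)
  }
  idx <- match(tolower(cases$drug), tolower(reference$drug))
  ft_disp <- ifelse(is.na(idx), cases$ft_printed, reference$ft_published[idx])
  unresolved <- is.na(idx) & is.na(cases$ft_printed)
  if (any(unresolved)) {
    stop("drug(s) not in reference table and carrying no reported factor: ",
         paste(unique(cases$drug[unresolved]), collapse = ", "),
         call. = FALSE)
  }
  f_exact <- compute_f(cases$p_conc, cases$am_conc)
  f_disp <- format_f(f_exact)
  rows <- data.frame(
    drug = cases$drug,
    p_conc = cases$p_conc,
    am_conc = cases$am_conc,
    f_exact = f_exact,
    f_displayed = f_disp,
    f_printed = cases$f_printed,
    ft_displayed = ft_disp,
    abs_diff = abs(f_disp - ft_disp),
    rel_diff = abs(f_disp - ft_disp) / ft_disp,
    t2_hours = cases$t2_hours,
    stringsAsFactors = FALSE
  )
  structure(list(
    cases = rows,
    delay_summary = delay_summary(cases$t2_hours)
  ), class = "pmr_case_comparison")
}

#' Summarize postmortem delays
#'
#' @param t2_hours numeric vector of postmortem delays (hours), > 0.
#' @return named list: `mean`, `sd` (sample SD; `NA` for a single delay),
#'   `median`, `min`, `max`, `n`.
#' @export
delay_summary <- function(t2_hours) {
  check_positive_numeric(t2_hours, "t2_hours")
  list(mean = mean(t2_hours), sd = stats::sd(t2_hours),
       median = stats::median(t2_hours), min = min(t2_hours),
       max = max(t2_hours), n = length(t2_hours))
}

#' Run the full model validation on a case and reference table
#'
#' Reproduces the model's validation analysis: the per-case comparison of
#' determined (`F`) versus theoretical (`Ft`) redistribution factors, the
#' postmortem-delay summary, and an ordinary least squares regression of the
#' theoretical factor on the determined factor. By default the regression
#' consumes the one-decimal displayed columns, which is the form in which
#' the factors are reported; `precision = "full"` regresses the
#' full-precision recomputed factor against the exact theoretical values
#' instead (theoretical values are then recomputed from the reference L/P
#' medians where available). In display mode the determined factor enters
#' the regression as recorded in the case table (`f_printed`), which is the
#' form the factors are reported in; the recomputed display is tabulated
#' alongside for auditing.
#'
#' @inheritParams compare_cases
#' @param precision `"display"` (default) or `"full"`.
#' @return an object of class `pmr_validation`: list with `comparison`
#'   (a `pmr_case_comparison`), `regression` (a `pmr_ols` of `ft ~ f`), and
#'   `precision`.
#' @examples
#' v <- run_validation(load_case_table(), load_reference_table())
#' v$regression
#' @export
run_validation <- function(cases, reference,
                           precision = c("display", "full")) {
  precision <- match.arg(precision)
  comparison <- compare_cases(cases, reference)
  rows <- comparison$cases
  if (precision == "display") {
    reg <- ols_fit(rows$f_printed, rows$ft_displayed)
  } else {
    idx <- match(tolower(rows$drug), tolower(reference$drug))
    lp <- reference$lp_median[idx]
    ft_y <- ifelse(!is.na(lp), ft_exact(ifelse(is.na(lp), 1, lp)),
                   rows$ft_displayed)
    reg <- ols_fit(rows$f_exact, ft_y)
  }
  structure(list(comparison = comparison, regression = reg,
                 precision = precision), class = "pmr_validation")
}

#' @export
print.pmr_validation <- function(x, ...) {
  rows <- x$comparison$cases
  cat(sprintf("Validation over %d paired cases (%s precision)\n",
              nrow(rows), x$precision))
  print(x$regression)
  ds <- x$comparison$delay_summary
  cat(sprintf(paste0("  postmortem delay: mean %.1f h (SD %.1f), ",
                     "median %.1f h, range %.1f-%.1f h\n"),
              ds$mean, ds$sd, ds$median, ds$min, ds$max))
  cat(sprintf("  displayed F within 0.1 of displayed Ft: %d/%d cases\n",
              sum(rows$abs_diff <= 0.1 + 1e-9), nrow(rows)))
  invisible(x)
}

#' Serialize a validation result to a machine-readable report
#'
#' @param x a `pmr_validation` object from [run_validation()].
#' @param path optional file path; if given, the JSON document is written
#'   there and the path returned invisibly.
#' @return the report as a list (or the path, invisibly, when `path` is
#'   given). Keys: `cases` (array of per-case rows), `regression`
#'   (`slope`, `intercept`, `r_squared`, `f_statistic`, `df`, `p_value`,
#'   `n`), `delay_summary`, `precision`.
#' @export
validation_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "pmr_validation"))
  reg <- x$regression
  report <- list(
    precision = x$precision,
    cases = x$comparison$cases,
    regression = list(slope = reg$slope, intercept = reg$intercept,
                      r_squared = reg$r_squared,
                      f_statistic = reg$f_statistic, df = reg$df,
                      p_value = reg$p_value, n = reg$n),
    delay_summary = x$comparison$delay_summary
  )
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
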