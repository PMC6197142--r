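# shared test utilities: in-code fixture builders and an independent OLS oracle

# simple-regression oracle via explicit normal equations; deliberately
# independent of ols_fit()'s lm() path
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2,
       f_statistic = r2 * (n - 2) / (1 - r2))
}

make_cases <- function(drug, p, am, f = NULL, ft = 1.0, t1 = 0, t2 = 10) {
  f <- if (is.null(f)) round(p / am, 1) else f
  df <- data.frame(drug = drug, p_conc = p, am_conc = am, f_printed = f,
                   ft_printed = ft, t1_minutes = t1, t2_hours = t2,
                   stringsAsFactors = FALSE)
  class(df) <- c("pmr_cases", "data.frame")
  df
}

make_reference <- function(drug, lp, n = 10L) {
  df <- data.frame(drug = drug, n_cases = n, lp_median = lp,
                   ft_published = format_ft(ft_exact(lp)),
                   ft_source = "computed", stringsAsFactors = FALSE)
  class(df) <- c("drug_reference", "data.frame")
  df
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
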