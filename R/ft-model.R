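#' Theoretical postmortem redistribution factor from an L/P ratio
#'
#' Computes the theoretical postmortem redistribution factor
#' \deqn{F_t = \sqrt{2 (R + 2.5)} / 2.6}
#' where \eqn{R} is a drug's characteristic liver-to-peripheral-blood
#' concentration ratio (L/kg). \eqn{F_t} is the dimensionless inflation
#' expected in a postmortem peripheral-blood concentration relative to the
#' antemortem whole-blood concentration; \eqn{F_t = 1} (at \eqn{R = 0.88})
#' means no expected redistribution.
#'
#' The function is continuous and strictly increasing in `r`, so drugs with
#' larger liver sequestration are always assigned a larger expected
#' redistribution.
#'
#' @param r numeric vector of liver/peripheral-blood ratios (L/kg); all
#'   values must be finite and strictly positive.
#' @return numeric vector of full-precision \eqn{F_t} values.
#' @seealso [format_ft()] for the reference-table display convention,
#'   [classify_propensity()] for the L/P propensity bands.
#' @examples
#' ft_exact(19.6)  # cyclobenzaprine: 2.55..., displayed 2.5
#' ft_exact(0.88)  # exactly 1: the no-redistribution anchor
#' @export
ft_exact <- function(r) {
  check_positive_numeric(r, "r")
  sqrt(2 * (r + 2.5)) / 2.6
}

#' Format a theoretical redistribution factor for reporting
#'
#' Applies the reference-table display convention: values at or above 1 are
#' truncated (floored) to one decimal place; values below 1 are rounded
#' half-up to two decimal places. Truncation rather than rounding above 1 is
#' deliberate — it is the convention the published reference values follow
#' (e.g. an exact factor of 1.991 is reported as 1.9, not 2.0) and it never
#' overstates the expected redistribution.
#'
#' A guard of 1e-9 absorbs binary floating-point representation error before
#' truncation, so an exact factor that is mathematically a round tenth
#' (such as the anchor \eqn{F_t(0.88) = 1}) is not pushed down a decimal.
#'
#' @param x numeric vector of positive full-precision factors.
#' @return numeric vector of displayed factors.
#' @examples
#' format_ft(ft_exact(10.9))  # 1.9 (truncated from 1.991)
#' format_ft(ft_exact(0.65)) # 0.97 (half-up at 2 decimals below 1)
#' @export
format_ft <- function(x) {
  check_positive_numeric(x, "x")
  ifelse(x >= 1, floor(x * 10 + 1e-9) / 10, round_half_up(x, 2L))
}

#' Determined postmortem redistribution factor from a paired case
#'
#' The observed factor \eqn{F = P / AM}: the ratio of the postmortem
#' peripheral-blood concentration to the antemortem whole-blood
#' concentration measured in the same individual. Both concentrations must
#' be in the same units (they cancel).
#'
#' @param p_conc postmortem peripheral-blood concentration(s), > 0.
#' @param am_conc antemortem whole-blood concentration(s), > 0, same units.
#' @param units_p,units_am optional unit labels; if both are given they must
#'   match (a ratio of unlike units is meaningless).
#' @return numeric vector of full-precision factors. Use [format_f()] for
#'   the one-decimal reporting convention.
#' @examples
#' compute_f(0.44, 0.33)  # methamphetamine case: 1.333..., displayed 1.3
#' @export
compute_f <- function(p_conc, am_conc, units_p = NULL, units_am = NULL) {
  check_positive_numeric(p_conc, "p_conc")
  check_positive_numeric(am_conc, "am_conc")
  if (!is.null(units_p) && !is.null(units_am) &&
      any(units_p != units_am)) {
    stop("unit mismatch: p_conc in ", paste(unique(units_p), collapse = ","),
         " but am_conc in ", paste(unique(units_am), collapse = ","),
         call. = FALSE)
  }
  p_conc / am_conc
}

#' @rdname compute_f
#' @param f numeric vector of positive full-precision determined factors.
#' @export
format_f <- function(f) {
  check_positive_numeric(f, "f")
  round_half_up(f, 1L)
}

#' Estimate an antemortem concentration from postmortem peripheral blood
#'
#' Inverts the redistribution relationship: \eqn{AM = P / F_t} (or \eqn{P/F}
#' when a case-determined factor is available). The estimate carries the
#' units of `p_conc`.
#'
#' The model was validated on autopsies performed within 48 hours of death;
#' if a postmortem delay is supplied and exceeds that window a warning is
#' emitted (not an error), because longer delays and decomposition can cause
#' additional, inconsistent redistribution.
#'
#' @param p_conc postmortem peripheral-blood concentration(s), > 0.
#' @param ft redistribution factor(s) to divide by (theoretical or
#'   determined), > 0.
#' @param t2_hours optional postmortem delay (death to autopsy, hours) used
#'   only for the applicability warning.
#' @return estimated antemortem concentration(s), same units as `p_conc`.
#' @examples
#' estimate_antemortem(0.56, 1.4)  # methadone: 0.40 mg/L (measured AM 0.39)
#' @export
estimate_antemortem <- function(p_conc, ft, t2_hours = NULL) {
  check_positive_numeric(p_conc, "p_conc")
  check_positive_numeric(ft, "ft")
  if (!is.null(t2_hours) && any(t2_hours > 48)) {
    warning("postmortem delay exceeds 48 h; the redistribution factor ",
            "model was established for autopsies within 48 hours and ",
            "estimates may be unreliable", call. = FALSE)
  }
  p_conc / ft
}

#' Classify a drug's redistribution propensity from its L/P ratio
#'
#' L/P ratios below 5 L/kg indicate little to no propensity for postmortem
#' redistribution; ratios of 20 L/kg and above indicate a propensity for
#' significant redistribution; the band between is moderate. Half-open
#' intervals \eqn{[5, 20)} and \eqn{[20, \infty)} make the boundaries
#' deterministic; the literature describes the significant threshold as a
#' 20-30 L/kg band, so ratios in that range are borderline calls.
#'
#' @param r numeric vector of L/P ratios (L/kg), > 0.
#' @return ordered factor with levels `minimal < moderate < significant`.
#' @examples
#' classify_propensity(c(2.3, 11.2, 76.0))
#' @export
classify_propensity <- function(r) {
  check_positive_numeric(r, "r")
  cut(r, breaks = c(0, 5, 20, Inf), right = FALSE,
      labels = c("minimal", "moderate", "significant"),
      ordered_result = TRUE)
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

check_positive_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("`", name, "` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and strictly positive", call. = FALSE)
  }
  invisible(x)
}
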