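#' Rank drugs by propensity for postmortem redistribution
#'
#' Orders a reference table by increasing displayed theoretical
#' redistribution factor, attaching each drug's propensity class (from its
#' L/P median, where available). Drugs sharing a displayed factor form a tie
#' group; within a group the order is alphabetical, a deterministic
#' convention — the reported factor carries one decimal, so no finer
#' ordering is meaningful within a group.
#'
#' @param entries a `drug_reference` data frame (see
#'   [load_reference_table()]); must be non-empty.
#' @return a `pmr_ranking` data frame with columns `rank`, `drug`,
#'   `ft_displayed`, `propensity` (ordered factor; `NA` for entries without
#'   an L/P median), `tie_group` (integer id shared by equal factors).
#' @examples
#' ranking <- rank_drugs(load_reference_table())
#' head(ranking)   # gabapentin first (0.97) ...
#' tail(ranking)   # ... sertraline last (4.8)
#' @export
rank_drugs <- function(entries) {
  stopifnot(inherits(entries, "drug_reference"))
  if (nrow(entries) == 0L) {
    stop("cannot rank an empty reference table", call. = FALSE)
  }
  ord <- order(entries$ft_published, tolower(entries$drug))
  ranked <- entries[ord, , drop = FALSE]
  propensity <- classify_propensity(ifelse(is.na(ranked$lp_median), 1,
                                           ranked$lp_median))
  propensity[is.na(ranked$lp_median)] <- NA
  out <- data.frame(
    rank = seq_len(nrow(ranked)),
    drug = ranked$drug,
    ft_displayed = ranked$ft_published,
    propensity = propensity,
    tie_group = match(ranked$ft_published, unique(ranked$ft_published)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("pmr_ranking", "data.frame")
  out
}

#' Render a ranking as aligned plain text
#'
#' @param x a `pmr_ranking` data frame.
#' @param ... unused.
#' @export
print.pmr_ranking <- function(x, ...) {
  cat(format_ranking(x), sep = "\n")
  invisible(x)
}

format_ranking <- function(x) {
  prop <- ifelse(is.na(x$propensity), "-", as.character(x$propensity))
  ft <- ifelse(x$ft_displayed < 1,
               formatC(x$ft_displayed, format = "f", digits = 2L),
               formatC(x$ft_displayed, format = "f", digits = 1L))
  c(sprintf("%4s  %-18s %5s  %s", "rank", "drug", "Ft", "propensity"),
    sprintf("%4d  %-18s %5s  %s", x$rank, x$drug, ft, prop))
}
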