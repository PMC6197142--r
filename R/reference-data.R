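#' Path to a packaged data fixture
#'
#' The package ships two curated plain-text tables: `"reference"`, the
#' 44-drug listing of median liver/peripheral-blood ratios with published
#' theoretical redistribution factors, and `"cases"`, 13 paired
#' antemortem/postmortem case records (nine drugs from nine cases) with
#' specimen-timing covariates.
#'
#' @param name `"reference"` or `"cases"`.
#' @return absolute path to the installed CSV file.
#' @examples
#' pmr_fixture("reference")
#' @export
pmr_fixture <- function(name = c("reference", "cases")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "pmrft",
                      mustWork = TRUE)
  path
}

#' Load a drug reference table
#'
#' Reads a CSV with columns `drug,n,lp_median,ft,ft_source` into a validated
#' reference table. Each row is one drug: its identifier, the number of
#' source cases behind the median, the median liver/peripheral-blood ratio
#' (L/kg), the published theoretical redistribution factor, and whether that
#' factor was computed from the L/P median or taken from literature.
#' Literature-sourced entries (ethanol, in the shipped table) carry no L/P
#' median; every computed entry must carry a positive one.
#'
#' @param source path to a CSV file; defaults to the packaged 44-drug table.
#' @return a `drug_reference` data frame with columns `drug`, `n_cases`,
#'   `lp_median`, `ft_published`, `ft_source`, in file order.
#' @examples
#' ref <- load_reference_table()
#' nrow(ref)  # 44
#' ref[ref$drug == "cyclobenzaprine", ]
#' @export
load_reference_table <- function(source = pmr_fixture("reference")) {
  raw <- read_pmr_csv(source, c("drug", "n", "lp_median", "ft", "ft_source"),
                      numeric_cols = c("n", "lp_median", "ft"))
  entries <- data.frame(
    drug = trimws(raw$drug),
    n_cases = raw$n,
    lp_median = raw$lp_median,
    ft_published = raw$ft,
    ft_source = trimws(raw$ft_source),
    stringsAsFactors = FALSE
  )
  if (nrow(entries) > 0L) {
    dup <- duplicated(tolower(entries$drug))
    if (any(dup)) {
      stop("duplicate drug entries (case-insensitive): ",
           paste(unique(entries$drug[dup]), collapse = ", "), call. = FALSE)
    }
    bad_src <- !entries$ft_source %in% c("computed", "literature")
    if (any(bad_src)) {
      stop("ft_source must be 'computed' or 'literature'; offending rows: ",
           paste(which(bad_src), collapse = ", "), call. = FALSE)
    }
    check_entry_positive(entries$ft_published, "ft")
    comp <- entries$ft_source == "computed"
    if (any(comp & is.na(entries$lp_median))) {
      stop("computed entries must carry a positive lp_median; missing for: ",
           paste(entries$drug[comp & is.na(entries$lp_median)],
                 collapse = ", "), call. = FALSE)
    }
    if (any(!comp & !is.na(entries$lp_median))) {
      stop("literature entries must not carry lp_median: ",
           paste(entries$drug[!comp & !is.na(entries$lp_median)],
                 collapse = ", "), call. = FALSE)
    }
    check_entry_positive(entries$lp_median[comp], "lp_median")
    n_ok <- is.na(entries$n_cases) |
      (entries$n_cases > 0 & entries$n_cases == round(entries$n_cases))
    if (!all(n_ok)) {
      stop("n must be a positive integer where present; offending rows: ",
           paste(which(!n_ok), collapse = ", "), call. = FALSE)
    }
  }
  class(entries) <- c("drug_reference", "data.frame")
  entries
}

#' Load a paired antemortem/postmortem case table
#'
#' Reads a CSV with columns `drug,p,am,f,ft,t1_min,t2_h`. Each record pairs
#' a postmortem peripheral-blood concentration `p` with the antemortem
#' whole-blood concentration `am` from the same individual (mg/L; g/dL for
#' ethanol), the determined and theoretical redistribution factors as
#' reported, the interval between the antemortem draw and death (`t1_min`,
#' minutes), and the postmortem delay from death to autopsy (`t2_h`, hours).
#'
#' @param source path to a CSV file; defaults to the packaged 13-case table.
#' @return a `pmr_cases` data frame with columns `drug`, `p_conc`,
#'   `am_conc`, `f_printed`, `ft_printed`, `t1_minutes`, `t2_hours`.
#' @examples
#' cases <- load_case_table()
#' cases[cases$drug == "methadone", ]
#' @export
load_case_table <- function(source = pmr_fixture("cases")) {
  raw <- read_pmr_csv(source, c("drug", "p", "am", "f", "ft", "t1_min", "t2_h"),
                      numeric_cols = c("p", "am", "f", "ft", "t1_min", "t2_h"))
  cases <- data.frame(
    drug = trimws(raw$drug),
    p_conc = raw$p,
    am_conc = raw$am,
    f_printed = raw$f,
    ft_printed = raw$ft,
    t1_minutes = raw$t1_min,
    t2_hours = raw$t2_h,
    stringsAsFactors = FALSE
  )
  if (nrow(cases) > 0L) {
    check_entry_positive(cases$p_conc, "p")
    check_entry_positive(cases$am_conc, "am")
    check_entry_positive(cases$f_printed, "f")
    check_entry_positive(cases$ft_printed, "ft")
    check_entry_positive(cases$t2_hours, "t2_h")
    if (anyNA(cases$t1_minutes) || any(cases$t1_minutes < 0)) {
      stop("t1_min must be non-negative", call. = FALSE)
    }
  }
  class(cases) <- c("pmr_cases", "data.frame")
  cases
}

#' Write a reference or case table to CSV
#'
#' Serializes a collection loaded (or constructed) in the package's table
#' schemas back to its CSV form, such that reloading yields an identical
#' collection. Collections with duplicate drug names are refused for
#' reference tables, mirroring load-time validation.
#'
#' @param x a `drug_reference` or `pmr_cases` data frame.
#' @param destination path to write to.
#' @return `destination`, invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_table(load_reference_table(), path)
#' @export
write_table <- function(x, destination) {
  UseMethod("write_table")
}

#' @export
write_table.drug_reference <- function(x, destination) {
  if (any(duplicated(tolower(x$drug)))) {
    stop("refusing to write reference table with duplicate drug names",
         call. = FALSE)
  }
  out <- data.frame(drug = x$drug, n = x$n_cases, lp_median = x$lp_median,
                    ft = x$ft_published, ft_source = x$ft_source)
  write_pmr_csv(out, destination)
}

#' @export
write_table.pmr_cases <- function(x, destination) {
  out <- data.frame(drug = x$drug, p = x$p_conc, am = x$am_conc,
                    f = x$f_printed, ft = x$ft_printed,
                    t1_min = x$t1_minutes, t2_h = x$t2_hours)
  write_pmr_csv(out, destination)
}

#' Validate a drug reference table against the model
#'
#' Produces a check report for a loaded reference table: the entry count,
#' the total number of source cases, and — the substantive check — per-drug
#' agreement between the published theoretical redistribution factor and the
#' value recomputed from the L/P median via [ft_exact()] and [format_ft()]
#' (literature-sourced entries are excluded from recomputation). On the
#' shipped table all checks pass: 44 entries, 867 source cases, 43/43
#' computed factors reproduced exactly.
#'
#' Failures are reported, not raised; the caller decides severity.
#'
#' @param entries a `drug_reference` data frame.
#' @param expected_n expected entry count (default: the shipped table's 44).
#' @param expected_total_cases expected sum of source cases (default 867).
#' @return data frame with columns `check`, `observed`, `expected`, `pass`,
#'   plus a `disagreements` attribute naming any drug whose recomputed
#'   factor differs from the published one.
#' @examples
#' validate_reference_fixture(load_reference_table())
#' @export
validate_reference_fixture <- function(entries, expected_n = 44L,
                                       expected_total_cases = 867L) {
  stopifnot(inherits(entries, "drug_reference"))
  comp <- entries$ft_source == "computed"
  recomputed <- format_ft(ft_exact(entries$lp_median[comp]))
  agree <- abs(recomputed - entries$ft_published[comp]) < 1e-9
  report <- data.frame(
    check = c("entry_count", "total_source_cases", "ft_recomputation"),
    observed = c(nrow(entries), sum(entries$n_cases, na.rm = TRUE),
                 sum(agree)),
    expected = c(expected_n, expected_total_cases, sum(comp)),
    stringsAsFactors = FALSE
  )
  report$pass <- report$observed == report$expected
  attr(report, "disagreements") <- entries$drug[comp][!agree]
  report
}

read_pmr_csv <- function(source, expected_cols, numeric_cols) {
  raw <- tryCatch(
    utils::read.csv(source, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse '", source, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(names(raw), expected_cols)) {
    stop("'", source, "' must have header: ",
         paste(expected_cols, collapse = ","), " (found: ",
         paste(names(raw), collapse = ","), ")", call. = FALSE)
  }
  for (col in numeric_cols) {
    txt <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & is.na(val))
    if (length(bad) > 0L) {
      stop("malformed numeric in column '", col, "' of '", source,
           "', data row(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- val
  }
  raw
}

write_pmr_csv <- function(df, destination) {
  ok <- tryCatch({
    utils::write.csv(df, destination, row.names = FALSE, quote = FALSE,
                     na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write '", destination, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(destination)
}

check_entry_positive <- function(x, name) {
  if (anyNA(x) || any(x <= 0)) {
    stop("column '", name, "' must be strictly positive; offending row(s): ",
         paste(which(is.na(x) | x <= 0), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
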