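# Cohort-level statistics: agreement between grading methods, 2x2
# association tests, and stratified positivity summaries.

#' Percent agreement between two grading methods
#'
#' @param manual,auto Equal-length vectors of grades (`0`/`1+`/`2+`/`3+`
#'   labels or integers 0-3), e.g. pathologist and automated scores.
#' @return A list of class `agreement_stats` with `n`, `n_match`,
#'   `percent_match` (exact, 0-100) and `kappa` (filled by
#'   [cohens_kappa()]; `NA` here).
#' @export
#' @examples
#' percent_agreement(c("2+", "1+", "0"), c("2+", "2+", "0"))
percent_agreement <- function(manual, auto) {
  g <- pair_grades(manual, auto)
  n <- length(g$manual)
  n_match <- sum(g$manual == g$auto)
  structure(list(n = n, n_match = n_match,
                 percent_match = 100 * n_match / n, kappa = NA_real_),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, digits = 0, ...) {
  cat(sprintf("agreement: %d/%d (%s%%)", x$n_match, x$n,
              format(round_half_up(x$percent_match, digits))))
  if (!is.na(x$kappa)) cat(sprintf(", Cohen's kappa %.3f", x$kappa))
  cat("\n")
  invisible(x)
}

#' Cohen's kappa between two graders
#'
#' Chance-corrected agreement over the four ordinal grade categories,
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the raters' marginals. Unweighted by
#' default; `weights = "linear"` applies linear disagreement weights for
#' the ordinal scale.
#'
#' @inheritParams percent_agreement
#' @param weights `"none"` (default) or `"linear"`.
#' @return A single number, at most 1. When both raters are constant and
#'   identical (`p_e = 1` with perfect agreement) kappa is defined as 1;
#'   `p_e = 1` with any disagreement is a degenerate-table error.
#' @export
cohens_kappa <- function(manual, auto, weights = c("none", "linear")) {
  weights <- match.arg(weights)
  g <- pair_grades(manual, auto)
  tab <- table(factor(g$manual, levels = GRADE_LABELS),
               factor(g$auto, levels = GRADE_LABELS))
  n <- sum(tab)
  p <- tab / n
  k <- nrow(tab)
  w <- if (weights == "none") diag(k) else
    1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    if (abs(1 - po) < .Machine$double.eps * 8) return(1)
    abort_ihc("chance agreement is 1 but raters disagree; kappa undefined",
              "ihc_degenerate_table")
  }
  (po - pe) / (1 - pe)
}

pair_grades <- function(manual, auto) {
  if (length(manual) == 0L || length(auto) == 0L)
    abort_ihc("no grade pairs supplied", "ihc_empty_input")
  if (length(manual) != length(auto))
    abort_ihc("`manual` and `auto` must have the same length",
              "ihc_invalid_input")
  if (anyNA(manual) || anyNA(auto))
    abort_ihc("missing grades are not allowed here", "ihc_invalid_input")
  m <- normalize_grade(manual); a <- normalize_grade(auto)
  list(manual = grade_label(m), auto = grade_label(a))
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square with one degree of freedom (optionally with the
#' Yates continuity correction), as used to test association between a
#' binary cohort split (e.g. ER status) and marker positivity.
#'
#' @param tab 2x2 matrix of non-negative counts, or `c(a, b, c, d)` filled
#'   by row.
#' @param yates Apply the Yates continuity correction (default `FALSE`).
#' @return A list of class `chisq_result` with `statistic`, `p_value`,
#'   `df` (= 1) and `yates`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(32, 4, 44, 28), 2, byrow = TRUE))
chi_square_2x2 <- function(tab, yates = FALSE) {
  if (!is.matrix(tab)) {
    if (length(tab) != 4L)
      abort_ihc("`tab` must be a 2x2 table", "ihc_invalid_input")
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  }
  if (any(dim(tab) != 2L) || anyNA(tab) || any(tab < 0) ||
      any(tab != floor(tab)))
    abort_ihc("`tab` must hold non-negative integer counts in 2x2 form",
              "ihc_invalid_input")
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort_ihc("a zero marginal makes the chi-square test degenerate",
              "ihc_degenerate_table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value), df = 1L, yates = yates),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square (df = 1%s): X^2 = %.4f, p = %.4g\n",
              if (x$yates) ", Yates-corrected" else "", x$statistic,
              x$p_value))
  invisible(x)
}

#' Stratified positivity summary of a cohort
#'
#' Tabulates marker positivity (grade 1+ or higher) and the per-grade
#' breakdown within each level of a stratifying field, plus an overall
#' row. Percentages are carried exactly (`percent_positive`) and rounded
#' for reporting (`percent_rounded`, half-up).
#'
#' @param records Data frame of cohort records with at least the grade
#'   column and, unless `stratify_by = NULL`, the stratifying column
#'   (e.g. `subtype`, `er`, `her2`, `menopause`, `chemo`).
#' @param stratify_by Name of the grouping column, or `NULL` for the
#'   overall row only.
#' @param grade_col Which grade column to summarize (default
#'   `"manual_grade"`).
#' @param digits Decimal places for `percent_rounded` (default 0).
#' @return A data frame of class `cohort_summary`: `stratum`, `n`,
#'   `n_positive`, `percent_positive`, `percent_rounded`, and grade counts
#'   `n_grade0`, `n_grade1`, `n_grade2`, `n_grade3`. Empty strata report
#'   `NA` percentages.
#' @export
cohort_summary <- function(records, stratify_by = NULL,
                           grade_col = "manual_grade", digits = 0) {
  if (!is.data.frame(records))
    abort_ihc("`records` must be a data frame", "ihc_invalid_input")
  if (!grade_col %in% names(records))
    abort_ihc(sprintf("grade column \"%s\" not found", grade_col),
              "ihc_config_error")
  if (!is.null(stratify_by) && !stratify_by %in% names(records))
    abort_ihc(sprintf("unknown stratify field \"%s\"", stratify_by),
              "ihc_config_error")

  strata <- if (is.null(stratify_by)) list(overall = records)
    else split(records, factor(records[[stratify_by]],
                               levels = unique(records[[stratify_by]])))
  one_row <- function(label, rec) {
    g <- if (nrow(rec)) normalize_grade(rec[[grade_col]]) else integer()
    by_grade <- tabulate(g + 1L, nbins = 4L)
    n <- length(g); npos <- sum(by_grade[2:4])
    pct <- if (n > 0) 100 * npos / n else NA_real_
    data.frame(stratum = label, n = n, n_positive = npos,
               percent_positive = pct,
               percent_rounded = if (n > 0) round_half_up(pct, digits)
                                 else NA_real_,
               n_grade0 = by_grade[1], n_grade1 = by_grade[2],
               n_grade2 = by_grade[3], n_grade3 = by_grade[4],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(names(strata), function(s) one_row(s, strata[[s]])),
    if (!is.null(stratify_by)) list(one_row("overall", records))
  ))
  rownames(out) <- NULL
  # self-consistency: percentages must recompute from the row's own counts
  ok <- is.na(out$percent_positive) |
    abs(out$percent_positive - 100 * out$n_positive / pmax(out$n, 1)) < 1e-9
  stopifnot(all(ok))
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Read or write a cohort record table
#'
#' CSV with the documented header `sample_id, subtype, er, pgr, her2,
#' menopause, chemo, manual_grade, auto_grade` (extra columns are kept;
#' missing optional columns are tolerated on read).
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a data frame; `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    abort_ihc(sprintf("cohort file not found: %s", path), "ihc_io_error")
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"sample_id" %in% names(rec))
    abort_ihc("cohort CSV must have a sample_id column", "ihc_io_error")
  rec
}

#' @rdname read_cohort
#' @param records Data frame of cohort records.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
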