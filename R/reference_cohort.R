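#' Reference hNIS breast-cancer cohort counts
#'
#' Subtype-by-grade counts for a published 108-case cohort of grade-III
#' infiltrating ductal carcinomas scored for human sodium iodide symporter
#' (hNIS) expression, used throughout the package as the worked example:
#' 25 ER+PgR+HER2- (14 scored 2+, 9 scored 1+, 2 negative), 11
#' ER+PgR+HER2+ (4/5/2), 27 ER-PgR-HER2+ (7/12/8) and 45 ER-PgR-HER2-
#' (8/17/20). No sample scored 3+.
#'
#' @return A data frame with columns `subtype`, `grade` and `n` suitable
#'   for [records_from_counts()] and [generate_cohort()].
#' @export
#' @examples
#' sum(hnis_reference_counts()$n)  # 108
hnis_reference_counts <- function() {
  data.frame(
    subtype = rep(c("ER+PgR+HER2-", "ER+PgR+HER2+",
                    "ER-PgR-HER2+", "ER-PgR-HER2-"), each = 3L),
    grade = rep(c("2+", "1+", "0"), times = 4L),
    n = c(14L, 9L, 2L,
          4L, 5L, 2L,
          7L, 12L, 8L,
          8L, 17L, 20L),
    stringsAsFactors = FALSE
  )
}

#' Expand a subtype-by-grade count table into per-sample records
#'
#' Builds one cohort record per counted sample, with receptor status
#' parsed from the subtype label and `manual_grade` set to the tabulated
#' grade. Useful for recomputing cohort summaries and association tests
#' directly from printed count tables, without images.
#'
#' @param counts Data frame with columns `subtype`, `grade`, `n`.
#' @return A cohort record data frame (`sample_id`, `subtype`, `er`,
#'   `pgr`, `her2`, `manual_grade`); `menopause`, `chemo` and
#'   `auto_grade` are `NA` since count tables do not carry them.
#' @export
#' @examples
#' rec <- records_from_counts(hnis_reference_counts())
#' cohort_summary(rec, "er")
records_from_counts <- function(counts) {
  if (!is.data.frame(counts) ||
      !all(c("subtype", "grade", "n") %in% names(counts)))
    abort_ihc("`counts` needs columns subtype, grade, n", "ihc_invalid_spec")
  grades <- normalize_grade(counts$grade)
  idx <- rep(seq_len(nrow(counts)), counts$n)
  if (!length(idx)) return(empty_records())
  st <- t(vapply(counts$subtype[idx], parse_subtype, character(3)))
  out <- data.frame(
    sample_id = sprintf("S%03d", seq_along(idx)),
    subtype = counts$subtype[idx],
    er = st[, "er"], pgr = st[, "pgr"], her2 = st[, "her2"],
    menopause = NA_character_, chemo = NA_character_,
    manual_grade = grade_label(grades[idx]),
    auto_grade = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
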