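# Four-zone histogram scoring of the pure-DAB intensity image.

GRADE_LABELS <- c("0", "1+", "2+", "3+")

#' Format a numeric grade as its clinical label
#'
#' @param grade Integer grade(s) in `0:3`.
#' @return Character vector using the standard labels `0`, `1+`, `2+`, `3+`.
#' @export
grade_label <- function(grade) {
  stopifnot(all(grade %in% 0:3))
  GRADE_LABELS[grade + 1L]
}

#' Zone histogram of a DAB intensity image
#'
#' Counts pixels of the separated DAB channel in the four scoring zones
#' and the excluded bright range. With the default boundaries the zones
#' are intensity 0-60 (grade 3+), 61-120 (2+), 121-170 (1+), 171-230 (0);
#' pixels above 230 are excluded as bright fatty tissue/background. All
#' ranges are closed at their printed integer endpoints.
#'
#' @param dab `H x W` integer matrix of DAB intensities in `[0, 255]`
#'   (from [separate_dab()]).
#' @param zones Four strictly increasing upper zone boundaries; the fourth
#'   is the exclusion cutoff.
#' @return A list of class `zone_histogram` with counts `n3`, `n2`, `n1`,
#'   `n0`, `n_excluded` and `total`.
#' @export
#' @examples
#' dab <- matrix(c(60L, 61L, 170L, 230L, 231L, 40L), 2, 3)
#' zone_histogram(dab)
zone_histogram <- function(dab, zones = c(60L, 120L, 170L, 230L)) {
  assert_channel_image(dab, "dab")
  if (length(zones) != 4L || any(diff(zones) <= 0))
    abort_ihc("`zones` must be four strictly increasing boundaries",
              "ihc_config_error")
  counts <- tabulate(as.integer(dab) + 1L, nbins = 256L)
  cum <- function(from, to) sum(counts[(from + 1L):(to + 1L)])
  h <- list(
    n3 = cum(0L, zones[1]),
    n2 = cum(zones[1] + 1L, zones[2]),
    n1 = cum(zones[2] + 1L, zones[3]),
    n0 = cum(zones[3] + 1L, zones[4]),
    n_excluded = if (zones[4] >= 255L) 0L else cum(zones[4] + 1L, 255L)
  )
  h$total <- h$n3 + h$n2 + h$n1 + h$n0 + h$n_excluded
  structure(h, zones = as.integer(zones), class = "zone_histogram")
}

#' @export
print.zone_histogram <- function(x, ...) {
  z <- attr(x, "zones")
  cat("DAB zone histogram\n")
  cat(sprintf("  3+ [0-%d]: %d   2+ [%d-%d]: %d   1+ [%d-%d]: %d   0 [%d-%d]: %d\n",
              z[1], x$n3, z[1] + 1, z[2], x$n2, z[2] + 1, z[3], x$n1,
              z[3] + 1, z[4], x$n0))
  cat(sprintf("  excluded (>%d): %d of %d pixels\n", z[4], x$n_excluded,
              x$total))
  invisible(x)
}

scoreable_counts <- function(h) {
  c(n3 = h$n3, n2 = h$n2, n1 = h$n1, n0 = h$n0)
}

#' Dominance rule: direct grading by a majority zone
#'
#' If one zone holds strictly more than `threshold` (default 66%) of the
#' scoreable (non-excluded) pixels, the image is graded by that zone
#' directly and the weighted formula is bypassed.
#'
#' @param h A `zone_histogram`.
#' @param threshold Dominance fraction in `(0, 1)`; strict inequality.
#' @return The dominant zone's grade (integer 0-3), or `NA_integer_` when
#'   no zone dominates.
#' @export
dominance_grade <- function(h, threshold = 0.66) {
  n <- scoreable_counts(h)
  scoreable <- sum(n)
  if (scoreable == 0)
    abort_ihc("all pixels are excluded; nothing to score",
              "ihc_no_scoreable_pixels")
  dominant <- which(n > threshold * scoreable)
  if (length(dominant) == 0L) return(NA_integer_)
  # at most one zone can strictly exceed a threshold >= 0.5
  c(3L, 2L, 1L, 0L)[dominant[1]]
}

#' Zone-weighted score
#'
#' The mean grade weight over scoreable pixels,
#' `(3*n3 + 2*n2 + 1*n1 + 0*n0) / (n3 + n2 + n1 + n0)`; excluded pixels do
#' not participate. Ranges over `[0, 3]`.
#'
#' @param h A `zone_histogram`.
#' @return A single number in `[0, 3]`.
#' @export
weighted_score <- function(h) {
  n <- scoreable_counts(h)
  scoreable <- sum(n)
  if (scoreable == 0)
    abort_ihc("all pixels are excluded; nothing to score",
              "ihc_no_scoreable_pixels")
  sum(n * c(3, 2, 1, 0)) / scoreable
}

#' Assign the four-tier grade from a zone histogram
#'
#' Applies the dominance rule first; when no zone dominates, the weighted
#' score is rounded (half-up by default) to the grade. Grades follow the
#' standard IHC tiers: negative (0), low positive (1+), positive (2+),
#' high positive (3+).
#'
#' @param h A `zone_histogram`.
#' @param dominance Dominance threshold, strict (default 0.66).
#' @param rounding `"half_up"` or `"half_even"` for the formula path.
#' @return A list of class `grade_result` with fields `grade` (integer
#'   0-3), `label`, `dominance_applied`, `weighted_score`, and
#'   `zone_fractions` (shares of scoreable pixels in zones 3+/2+/1+/0).
#' @export
assign_grade <- function(h, dominance = 0.66, rounding = "half_up") {
  n <- scoreable_counts(h)
  ws <- weighted_score(h)  # errors if nothing scoreable
  dom <- dominance_grade(h, dominance)
  if (!is.na(dom)) {
    grade <- dom
  } else {
    grade <- as.integer(switch(rounding,
      half_up = round_half_up(ws),
      half_even = round(ws),
      abort_ihc("unknown rounding mode", "ihc_config_error")))
  }
  structure(list(
    grade = grade,
    label = grade_label(grade),
    dominance_applied = !is.na(dom),
    weighted_score = ws,
    zone_fractions = n / sum(n)
  ), class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf("IHC grade: %s (%s; weighted score %.3f)\n", x$label,
              if (x$dominance_applied) "dominant zone" else "weighted formula",
              x$weighted_score))
  invisible(x)
}

#' Stained-area fraction and pathologist category
#'
#' Computes the fraction of scoreable (non-excluded) pixels at or below
#' the staining threshold and maps it to the pathologist's area
#' categories: negative (< 10%), focal (10-20%), patchy (20-70%),
#' diffused (>= 70%).
#'
#' @param dab `H x W` DAB intensity matrix.
#' @param stain_threshold Intensity at or below which a pixel counts as
#'   stained (default 170: any positive zone).
#' @param exclusion Intensities strictly above this are excluded
#'   (default 230).
#' @return A list of class `stained_area_result` with `stained_fraction`
#'   and `category`.
#' @export
stained_area <- function(dab, stain_threshold = 170, exclusion = 230) {
  assert_channel_image(dab, "dab")
  scoreable <- sum(dab <= exclusion)
  if (scoreable == 0)
    abort_ihc("all pixels are excluded; nothing to score",
              "ihc_no_scoreable_pixels")
  frac <- sum(dab <= stain_threshold) / scoreable
  structure(list(stained_fraction = frac, category = area_category(frac)),
            class = "stained_area_result")
}

area_category <- function(frac) {
  stopifnot(is.numeric(frac), frac >= 0, frac <= 1)
  if (frac < 0.10) "negative"
  else if (frac < 0.20) "focal"
  else if (frac < 0.70) "patchy"
  else "diffused"
}

#' @export
print.stained_area_result <- function(x, ...) {
  cat(sprintf("stained area: %.1f%% (%s)\n", 100 * x$stained_fraction,
              x$category))
  invisible(x)
}

#' Score one IHC image end to end
#'
#' Runs the full pipeline on an RGB micrograph: DAB/hematoxylin
#' de-convolution, zone histogramming of the pure-DAB channel, grade
#' assignment (dominance rule, then weighted formula) and stained-area
#' categorisation.
#'
#' @param img `H x W x 3` RGB intensity array, or a file path readable by
#'   [read_ihc_image()].
#' @param config An [ihc_config()] (or plain list of its fields).
#' @param keep_channels Keep the separated `dab`/`hematoxylin` channel
#'   images in the result (default `FALSE` to save memory in batches).
#' @return A list of class `ihc_score` with elements `histogram`
#'   (`zone_histogram`), `grade` (`grade_result`), `area`
#'   (`stained_area_result`), and optionally `channels`.
#' @export
#' @examples
#' img <- render_ihc(grade_region_spec(2L), size = c(32, 32), seed = 1)
#' score_image(img$rgb)$grade$label
score_image <- function(img, config = ihc_config(), keep_channels = FALSE) {
  cfg <- as_ihc_config(config)
  if (is.character(img)) img <- read_ihc_image(img)
  ch <- separate_dab(img, cfg$stain_matrix, cfg$background, cfg$epsilon)
  h <- zone_histogram(ch$dab, cfg$zones)
  res <- list(
    histogram = h,
    grade = assign_grade(h, cfg$dominance, cfg$rounding),
    area = stained_area(ch$dab, cfg$area_threshold, cfg$zones[4])
  )
  if (keep_channels) res$channels <- ch
  structure(res, class = "ihc_score")
}

#' @export
print.ihc_score <- function(x, ...) {
  print(x$grade)
  print(x$area)
  print(x$histogram)
  invisible(x)
}

#' Average the weighted scores of several images of one sample
#'
#' When a section is heterogeneous, several fields of view can be captured
#' and their weighted scores averaged; the mean score is then rounded to a
#' grade. The dominance rule is a per-image device and is not applied at
#' the aggregate level.
#'
#' @param scores Numeric vector of per-image weighted scores in `[0, 3]`.
#' @param rounding `"half_up"` or `"half_even"`.
#' @return A `grade_result` whose `weighted_score` is the mean score and
#'   whose `zone_fractions` are `NA`.
#' @export
average_grade <- function(scores, rounding = "half_up") {
  if (length(scores) == 0L)
    abort_ihc("no scores to average", "ihc_empty_input")
  if (!is.numeric(scores) || anyNA(scores) || any(scores < 0 | scores > 3))
    abort_ihc("scores must be numbers in [0, 3]", "ihc_invalid_input")
  m <- mean(scores)
  grade <- as.integer(switch(rounding,
    half_up = round_half_up(m),
    half_even = round(m),
    abort_ihc("unknown rounding mode", "ihc_config_error")))
  structure(list(grade = grade, label = grade_label(grade),
                 dominance_applied = FALSE, weighted_score = m,
                 zone_fractions = rep(NA_real_, 4)),
            class = "grade_result")
}
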