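# Color de-convolution: OD transform, linear unmixing, stain channel images.

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert transform per channel,
#' `OD = -log10(max(I, epsilon) / I0)`, where `I0` is the per-channel
#' white level. The intensity floor `epsilon` (default 1) bounds the OD at
#' about 2.4 without biasing values of 1 and above; negative OD (pixels
#' brighter than the background) is clamped to 0.
#'
#' @param img `H x W x 3` array of intensities in `[0, 255]`.
#' @param background Per-channel white level, three values in `(0, 255]`,
#'   or `"estimate"` for the per-image 99th-percentile channel value.
#' @param epsilon Positive intensity floor avoiding `log(0)`.
#' @return `H x W x 3` array of non-negative optical densities.
#' @export
rgb_to_od <- function(img, background = c(255, 255, 255), epsilon = 1) {
  assert_rgb_image(img)
  bg <- resolve_background(img, background)
  od <- array(0, dim = dim(img))
  for (ch in 1:3)
    od[, , ch] <- -log10(pmax(img[, , ch], epsilon) / bg[ch])
  od[od < 0] <- 0
  od
}

resolve_background <- function(img, background) {
  if (identical(background, "estimate")) {
    bg <- vapply(1:3, function(ch)
      stats::quantile(img[, , ch], 0.99, names = FALSE), numeric(1))
    bg <- pmax(bg, 1)
  } else {
    bg <- background
    if (!is.numeric(bg) || length(bg) != 3L || anyNA(bg))
      abort_ihc("`background` must be three numeric white levels",
                "ihc_invalid_background")
    if (any(bg <= 0) || any(bg > 255))
      abort_ihc("`background` values must lie in (0, 255]",
                "ihc_invalid_background")
  }
  bg
}

#' Unmix optical densities into per-stain concentrations
#'
#' Solves the linear mixing model `OD = M %*% c` per pixel, where the
#' columns of `M` are the unit stain vectors, giving one concentration
#' plane per stain. Negative concentrations (noise below the stain plane)
#' are clamped to 0.
#'
#' @param od `H x W x 3` optical-density array from [rgb_to_od()].
#' @param stains 3x3 stain matrix (see [stain_matrix()]).
#' @return A list of three `H x W` concentration matrices named
#'   `hematoxylin`, `dab`, `residual` (or the stain matrix's column names).
#' @export
deconvolve <- function(od, stains = stain_matrix("hdab")) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    abort_ihc("`od` must be an H x W x 3 array", "ihc_invalid_image")
  if (!is.matrix(stains) || any(dim(stains) != c(3L, 3L)) ||
      !is_invertible(stains))
    abort_ihc("stain matrix must be an invertible 3 x 3 matrix",
              "ihc_degenerate_stains")
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)             # pixels x channels
  conc <- flat %*% t(solve(stains))         # pixels x stains
  conc[conc < 0] <- 0
  nm <- colnames(stains)
  if (is.null(nm)) nm <- c("hematoxylin", "dab", "residual")
  out <- lapply(1:3, function(s) matrix(conc[, s], d[1], d[2]))
  names(out) <- nm
  out
}

#' Render a concentration plane as an 8-bit stain intensity image
#'
#' Inverts the Beer-Lambert law for a single stain:
#' `I = clamp(round(255 * 10^(-c)), 0, 255)` with round-half-away-from-zero,
#' so 0 is the darkest (most stained) and 255 the lightest shade.
#'
#' @param conc `H x W` matrix of non-negative stain concentrations.
#' @return `H x W` integer matrix of intensities in `[0, 255]`.
#' @export
concentration_to_intensity <- function(conc) {
  if (!is.numeric(conc) || anyNA(conc) || min(conc) < 0)
    abort_ihc("`conc` must be non-negative and finite", "ihc_invalid_image")
  i <- round_half_up(255 * 10^(-conc))
  i[i > 255] <- 255
  mode(i) <- "integer"
  if (is.null(dim(i))) dim(i) <- dim(conc)
  i
}

#' Separate the DAB and hematoxylin channels of an IHC image
#'
#' Full color de-convolution: optical-density transform, unmixing against
#' the stain matrix, and conversion of the DAB and hematoxylin
#' concentration planes back to 8-bit intensity images (darker = more
#' stain). The DAB channel is the input to [zone_histogram()] and
#' [score_image()].
#'
#' @inheritParams rgb_to_od
#' @param stains 3x3 stain matrix or anything accepted by [stain_matrix()].
#' @return A list with integer `H x W` matrices `dab` and `hematoxylin`.
#' @export
#' @examples
#' img <- array(200L, dim = c(4, 4, 3))  # light gray patch
#' separate_dab(img)$dab[1, 1]
separate_dab <- function(img, stains = stain_matrix("hdab"),
                         background = c(255, 255, 255), epsilon = 1) {
  if (!is.matrix(stains)) stains <- stain_matrix(stains)
  od <- rgb_to_od(img, background, epsilon)
  conc <- deconvolve(od, stains)
  list(dab = concentration_to_intensity(conc$dab),
       hematoxylin = concentration_to_intensity(conc$hematoxylin))
}
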