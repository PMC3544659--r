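#' Pipeline configuration
#'
#' Builds a validated configuration for the scoring pipeline. All arguments
#' have defaults matching the published method: zone boundaries at
#' intensities 60/120/170/230 (grades 3+/2+/1+/0), pixels above the last
#' boundary excluded as fatty tissue/background, and a 66% dominance
#' threshold.
#'
#' @param zones Integer vector of four strictly increasing upper zone
#'   boundaries in `[0, 255]`. `zones[4]` is also the exclusion cutoff:
#'   intensities above it are not scored.
#' @param dominance Dominance threshold in `(0, 1)`: a zone whose share of
#'   scoreable pixels strictly exceeds this grades the image directly.
#' @param rounding `"half_up"` (default, 1.5 rounds to 2+) or `"half_even"`,
#'   used when mapping the weighted score to a grade.
#' @param stains Stain matrix: the preset name `"hdab"`, a 3x3 numeric
#'   matrix of column stain vectors, or a path to a text file with three
#'   rows of three numbers (see [stain_matrix()]).
#' @param background Per-channel white level: a 3-vector in `(0, 255]`, or
#'   `"estimate"` to use the 99th-percentile channel value of each image.
#' @param epsilon Intensity floor used in the optical-density transform to
#'   avoid `log(0)`; transmitted intensity is clamped below at this value.
#' @param area_threshold Intensity at or below which a pixel counts as
#'   "stained" for the stained-area categories (default 170, i.e. any
#'   positive zone).
#'
#' @return A list of class `ihc_config`.
#' @seealso [read_ihc_config()] to load a configuration from a YAML file.
#' @export
#' @examples
#' cfg <- ihc_config()
#' cfg$zones
ihc_config <- function(zones = c(60L, 120L, 170L, 230L),
                       dominance = 0.66,
                       rounding = c("half_up", "half_even"),
                       stains = "hdab",
                       background = c(255, 255, 255),
                       epsilon = 1,
                       area_threshold = 170) {
  rounding <- match.arg(rounding)
  cfg <- list(zones = zones, dominance = dominance, rounding = rounding,
              stains = stains, background = background, epsilon = epsilon,
              area_threshold = area_threshold)
  validate_config(cfg)
}

#' Validate and normalize a configuration
#'
#' Fills defaults for missing fields, resolves the stain matrix, and
#' enforces the configuration invariants (strictly increasing zone
#' boundaries within `[0, 255]`, dominance threshold in `(0, 1)`).
#'
#' @param cfg A named list of configuration fields (possibly partial), or
#'   an `ihc_config` object.
#' @return A normalized `ihc_config` list with a resolved 3x3 stain matrix.
#' @export
validate_config <- function(cfg = list()) {
  if (!is.list(cfg))
    abort_ihc("configuration must be a named list", "ihc_config_error")
  defaults <- list(zones = c(60L, 120L, 170L, 230L), dominance = 0.66,
                   rounding = "half_up", stains = "hdab",
                   background = c(255, 255, 255), epsilon = 1,
                   area_threshold = 170)
  unknown <- setdiff(names(cfg), c(names(defaults), "stain_matrix"))
  if (length(unknown))
    abort_ihc(paste0("unknown configuration field(s): ",
                     paste(unknown, collapse = ", ")), "ihc_config_error")
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])

  z <- cfg$zones
  if (!is.numeric(z) || length(z) != 4L || anyNA(z) || any(z != floor(z)))
    abort_ihc("`zones` must be four integers", "ihc_config_error")
  if (any(diff(z) <= 0) || z[1] < 0 || z[4] > 255)
    abort_ihc("`zones` must be strictly increasing within [0, 255]",
              "ihc_config_error")
  cfg$zones <- as.integer(z)

  if (!is.numeric(cfg$dominance) || length(cfg$dominance) != 1L ||
      is.na(cfg$dominance) || cfg$dominance <= 0 || cfg$dominance >= 1)
    abort_ihc("`dominance` must be a single number in (0, 1)",
              "ihc_config_error")
  if (!cfg$rounding %in% c("half_up", "half_even"))
    abort_ihc("`rounding` must be \"half_up\" or \"half_even\"",
              "ihc_config_error")

  bg <- cfg$background
  if (!(identical(bg, "estimate"))) {
    if (!is.numeric(bg) || length(bg) != 3L || anyNA(bg) ||
        any(bg <= 0) || any(bg > 255))
      abort_ihc("`background` must be three values in (0, 255] or \"estimate\"",
                "ihc_config_error")
  }
  if (!is.numeric(cfg$epsilon) || length(cfg$epsilon) != 1L ||
      is.na(cfg$epsilon) || cfg$epsilon <= 0)
    abort_ihc("`epsilon` must be a positive number", "ihc_config_error")
  if (!is.numeric(cfg$area_threshold) || length(cfg$area_threshold) != 1L ||
      is.na(cfg$area_threshold) || cfg$area_threshold < 0 ||
      cfg$area_threshold > cfg$zones[4])
    abort_ihc("`area_threshold` must lie in [0, zones[4]]", "ihc_config_error")

  cfg$stain_matrix <- stain_matrix(cfg$stains)
  class(cfg) <- "ihc_config"
  cfg
}

#' Read a configuration from a YAML file
#'
#' Accepts the same fields as [ihc_config()]; missing fields take the
#' defaults. The `stains` field may name a preset or a path (relative paths
#' are resolved against the config file's directory).
#'
#' @param path Path to a YAML key-value file.
#' @return A normalized `ihc_config` list.
#' @export
read_ihc_config <- function(path) {
  if (!file.exists(path))
    abort_ihc(sprintf("config file not found: %s", path), "ihc_config_error")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.null(cfg$stains) && is.character(cfg$stains) &&
      !identical(cfg$stains, "hdab") && !file.exists(cfg$stains)) {
    local <- file.path(dirname(path), cfg$stains)
    if (file.exists(local)) cfg$stains <- local
  }
  validate_config(cfg)
}

#' @export
print.ihc_config <- function(x, ...) {
  cat("IHC scoring configuration\n")
  cat(sprintf("  zones (3+/2+/1+/0 upper bounds): %s; excluded above %d\n",
              paste(x$zones, collapse = "/"), x$zones[4]))
  cat(sprintf("  dominance threshold: %g, rounding: %s\n",
              x$dominance, x$rounding))
  bg <- if (identical(x$background, "estimate")) "per-image estimate"
        else paste(x$background, collapse = ",")
  cat(sprintf("  background: %s, epsilon: %g, stained-area threshold: %g\n",
              bg, x$epsilon, x$area_threshold))
  invisible(x)
}

as_ihc_config <- function(cfg) {
  if (inherits(cfg, "ihc_config")) cfg else validate_config(cfg)
}
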