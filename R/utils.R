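# Internal helpers: classed errors, rounding, validation.

abort_ihc <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ihc_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# round-half-away-from-zero; base round() is half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

#' @keywords internal
assert_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort_ihc(sprintf("`%s` must be an H x W x 3 array", arg), "ihc_invalid_image")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    abort_ihc(sprintf("`%s` has zero pixels", arg), "ihc_empty_input")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    abort_ihc(sprintf("`%s` must hold intensities in [0, 255]", arg),
              "ihc_invalid_image")
  invisible(img)
}

assert_channel_image <- function(x, arg = "dab") {
  if (!is.matrix(x) && !(is.array(x) && length(dim(x)) == 2L))
    abort_ihc(sprintf("`%s` must be an H x W matrix", arg), "ihc_invalid_image")
  if (length(x) == 0L)
    abort_ihc(sprintf("`%s` has zero pixels", arg), "ihc_empty_input")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    abort_ihc(sprintf("`%s` must hold intensities in [0, 255]", arg),
              "ihc_invalid_image")
  invisible(x)
}
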