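#' Stain optical-density matrix
#'
#' Builds the 3x3 matrix of unit-length stain vectors used for color
#' de-convolution. Columns are, in order, hematoxylin, DAB, and a residual
#' stain; rows are the R, G, B optical-density components. The `"hdab"`
#' preset uses the widely published Ruifrok-derived H-DAB vectors,
#' hematoxylin (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), with
#' the residual column their normalized cross product.
#'
#' @param stains One of: the preset name `"hdab"`; a 3x2 or 3x3 numeric
#'   matrix whose *columns* are stain vectors (a missing third column is
#'   completed with the normalized cross product of the first two); or a
#'   path to a whitespace/comma-delimited text file with one stain vector
#'   per row (two or three rows of three numbers). Vectors are
#'   L2-normalized automatically.
#' @return A 3x3 numeric matrix with unit-norm columns, `dimnames`
#'   `list(c("R","G","B"), c("hematoxylin","dab","residual"))`.
#' @export
#' @examples
#' stain_matrix("hdab")
stain_matrix <- function(stains = "hdab") {
  if (is.matrix(stains)) {
    m <- stains
  } else if (is.character(stains) && length(stains) == 1L) {
    if (stains == "hdab") {
      m <- cbind(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778))
    } else if (file.exists(stains)) {
      rows <- utils::read.table(stains, sep = "", comment.char = "#")
      if (ncol(rows) == 1L)
        rows <- utils::read.table(stains, sep = ",", comment.char = "#")
      m <- t(as.matrix(rows))
    } else {
      abort_ihc(sprintf("unknown stain preset or missing file: %s", stains),
                "ihc_config_error")
    }
  } else {
    abort_ihc("`stains` must be a preset name, matrix, or file path",
              "ihc_config_error")
  }

  if (nrow(m) != 3L || !ncol(m) %in% 2:3 || anyNA(m) || !is.numeric(m))
    abort_ihc("stain matrix must be 3 x 2 or 3 x 3 numeric",
              "ihc_config_error")
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0))
    abort_ihc("stain vectors must be non-zero", "ihc_degenerate_stains")
  m <- sweep(m, 2, norms, "/")
  if (ncol(m) == 2L) {
    res <- cross3(m[, 1], m[, 2])
    if (sqrt(sum(res^2)) < 1e-8)
      abort_ihc("stain vectors are collinear; cannot build residual",
                "ihc_degenerate_stains")
    m <- cbind(m, res / sqrt(sum(res^2)))
  }
  if (!is_invertible(m))
    abort_ihc("stain matrix is singular or near-singular",
              "ihc_degenerate_stains")
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "dab", "residual"))
  m
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_invertible <- function(m, max_condition = 1e8) {
  rc <- tryCatch(rcond(m), error = function(e) 0)
  is.finite(rc) && rc > 1 / max_condition
}
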