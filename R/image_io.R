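#' Read an 8-bit RGB brightfield image
#'
#' Reads PNG or TIFF (and, when the EBImage package is installed, JPEG)
#' micrographs into an `H x W x 3` integer array of intensities in
#' `[0, 255]`. An alpha channel, if present, is dropped with a warning;
#' grayscale images are expanded to three identical channels.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.jpg`/`.jpeg` file.
#' @return An `H x W x 3` array of integers in `[0, 255]`.
#' @export
read_ihc_image <- function(path) {
  if (!file.exists(path))
    abort_ihc(sprintf("image file not found: %s", path), "ihc_io_error")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = read_jpeg(path),
    abort_ihc(sprintf("unsupported image format: .%s", ext), "ihc_io_error")
  )
  if (is.list(px)) px <- px[[1]]  # multi-page TIFF: first page
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3] == 4L) {
    warning(sprintf("dropping alpha channel of %s", basename(path)),
            call. = FALSE)
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] == 2L) {  # gray + alpha
    warning(sprintf("dropping alpha channel of %s", basename(path)),
            call. = FALSE)
    px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  }
  img <- array(as.integer(round_half_up(px * 255)), dim = dim(px))
  assert_rgb_image(img, "image")
  img
}

read_jpeg <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    abort_ihc("JPEG reading requires the EBImage package", "ihc_io_error")
  px <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores images x-major; transpose back to row-major
  if (length(dim(px)) == 3L) aperm(px, c(2, 1, 3)) else t(px)
}

#' Write a single-stain grayscale image
#'
#' Writes a separated stain channel (e.g. the pure-DAB image from
#' [separate_dab()]) as an 8-bit grayscale PNG or TIFF for visual QC.
#'
#' @param channel `H x W` matrix of intensities in `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_stain_image <- function(channel, path) {
  assert_channel_image(channel, "channel")
  ext <- tolower(tools::file_ext(path))
  v <- channel / 255
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    abort_ihc(sprintf("unsupported output format: .%s", ext), "ihc_io_error")
  )
  invisible(path)
}

#' Write an RGB image
#'
#' Writes an `H x W x 3` integer intensity array (e.g. a [render_ihc()]
#' synthetic image) as an 8-bit PNG or TIFF.
#'
#' @param img `H x W x 3` array of intensities in `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  assert_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  v <- img / 255
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    abort_ihc(sprintf("unsupported output format: .%s", ext), "ihc_io_error")
  )
  invisible(path)
}
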