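# Small image IO helpers. RGB images are H x W x 3 arrays in [0,1]; label maps
# are integer matrices with raw ids 0..7 stored in 8-bit single-channel PNGs.

#' Read and write label maps as single-channel 8-bit PNG
#'
#' @param labels Integer matrix of label ids 0..7.
#' @param path File path.
#' @return `read_label_png` returns an integer matrix; `write_label_png`
#'   invisibly returns `path`.
#' @export
write_label_png <- function(labels, path) {
  stopifnot_labels(labels)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  stopifnot_labels(m)
}

#' Read an RGB image (PNG or TIFF) as an H x W x 3 array in \[0,1\]
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric array H x W x 3.
#' @export
read_rgb <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    EBImage::imageData(EBImage::transpose(EBImage::readImage(path)))
  else png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  x[, , 1:3, drop = FALSE]
}

#' Write an RGB array to PNG
#' @param image H x W x 3 array in \[0,1\].
#' @param path Output path.
#' @export
write_rgb <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
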