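#' Read a raster image as an 8-bit matrix or RGB array
#'
#' Reads PNG and TIFF natively; JPEG is read through \pkg{EBImage} when that
#' package is installed. Greyscale images come back as a numeric matrix with
#' values in \code{[0, 255]}; colour images as a \code{height x width x 3}
#' array. An alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return A numeric matrix (grey) or 3-slice array (RGB), intensities 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input needs the EBImage package", call. = FALSE)
      x <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores (x, y[, channel]); transpose to (row, col)
      if (length(dim(x)) == 2L) t(x) else aperm(x, c(2L, 1L, 3L))
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (length(dim(raw)) == 3L) {
    raw <- raw[, , 1L]
  }
  round_half_up(raw * 255)
}

#' Write a matrix or RGB array as a PNG file
#'
#' @param img Numeric matrix (grey, values 0-255 or 0/1) or RGB array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  v <- img
  if (max(v) <= 1) v <- v * 255
  png::writePNG(clamp(v / 255, 0, 1), target = path)
  invisible(path)
}
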