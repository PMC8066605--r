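# Pre-processing: greyscale conversion, Gaussian smoothing and contrast
# enhancement. The goal of this stage is a high-contrast, low-noise 8-bit
# image whose tube edges survive gradient-based detection.

#' Convert an RGB image to greyscale
#'
#' Averages the three colour channels per pixel, `(R + G + B) / 3`,
#' rounding half-up to an integer level. Optional channel weights let a
#' vessel that is over-represented in one channel contribute more: with
#' weights \eqn{w}, the output is the weighted mean normalised by
#' \eqn{\sum w}.
#'
#' @param img A `height x width x 3` numeric array, values in `[0, 255]`.
#' @param weights Optional length-3 non-negative weights with a positive sum.
#' @return A numeric matrix (grey image), integer values in `[0, 255]`.
#' @export
to_grayscale <- function(img, weights = NULL) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("`img` must have exactly 3 channels (height x width x 3)", call. = FALSE)
  if (is.null(weights)) weights <- c(1, 1, 1)
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0)
    stop("`weights` must be 3 non-negative values with a positive sum",
         call. = FALSE)
  g <- (img[, , 1] * weights[1] + img[, , 2] * weights[2] +
          img[, , 3] * weights[3]) / sum(weights)
  out <- clamp(round_half_up(g), 0, 255)
  assert_grey_image(out)
}

#' Discrete 2D Gaussian smoothing kernel
#'
#' Samples \eqn{G(x, y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/2\sigma^2}}
#' on the integer grid `[-radius, radius]^2`. With `normalize = TRUE`
#' (the default) the weights are rescaled to sum to 1 so that convolution
#' preserves the global intensity level.
#'
#' @param sigma Spread in pixels, `> 0`.
#' @param radius Half-width in pixels, `>= 1`; defaults to `ceiling(3 * sigma)`.
#' @param normalize Rescale weights to unit sum?
#' @return A `(2 radius + 1)` square matrix with attributes `sigma`, `radius`.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma), normalize = TRUE) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k2 <- outer(k, k) / (2 * pi * sigma^2)
  if (normalize) k2 <- k2 / sum(k2)
  structure(k2, sigma = sigma, radius = radius)
}

#' Gaussian smoothing of a grey image
#'
#' Convolves the image with the normalised discrete Gaussian of
#' [gaussian_kernel()], using reflect-101 border padding (mirror about the
#' edge sample) so that no artificial dark frame is introduced at the image
#' border. The separable form is used internally; the result is rounded
#' half-up back to integer levels.
#'
#' @param img Grey image matrix, values in `[0, 255]`.
#' @param sigma Gaussian spread in pixels, `> 0` (default 2).
#' @param radius Kernel half-width (default `ceiling(3 * sigma)`).
#' @return Smoothed grey image matrix.
#' @export
gaussian_smooth <- function(img, sigma = 2, radius = ceiling(3 * sigma)) {
  assert_grey_image(img)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  x <- seq.int(-radius, radius)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  p <- pad_reflect101(img, radius)
  nr <- nrow(img); nc <- ncol(img)
  # rows pass
  tmp <- matrix(0, nr, nc + 2L * radius)
  for (j in seq_along(k1))
    tmp <- tmp + k1[j] * p[seq.int(j, nr + j - 1L), , drop = FALSE]
  # columns pass
  out <- matrix(0, nr, nc)
  for (j in seq_along(k1))
    out <- out + k1[j] * tmp[, seq.int(j, nc + j - 1L), drop = FALSE]
  clamp(round_half_up(out), 0, 255)
}

#' Intensity histogram, cumulative distribution and remapping tables
#'
#' Summarises the 8-bit intensity distribution of a grey image: counts per
#' level, the cumulative distribution function
#' \eqn{cdf(n) = \sum_{i \le n} c_i / c}, the observed extrema, the linear
#' stretch factor \eqn{E_f = 255 / (GreyMax - GreyMin)} and the equalisation
#' map \eqn{B_{hist}(n) = \mathrm{round}((L-1) \, cdf(n))}.
#'
#' @param img Grey image matrix.
#' @param L Number of output levels for the equalisation map (default 256).
#' @return An object of class `intensity_histogram`: a list with `counts`
#'   (levels 0-255), `cdf`, `grey_min`, `grey_max`, `E_f`, `bhist`, `L`.
#' @export
intensity_histogram <- function(img, L = 256L) {
  assert_grey_image(img)
  if (L < 2) stop("`L` must be >= 2", call. = FALSE)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  gmin <- min(img); gmax <- max(img)
  structure(list(
    counts = counts,
    cdf = cdf,
    grey_min = gmin,
    grey_max = gmax,
    E_f = if (gmax > gmin) 255 / (gmax - gmin) else NA_real_,
    bhist = round_half_up((L - 1) * cdf),
    L = as.integer(L)
  ), class = "intensity_histogram")
}

#' Linear contrast stretch to the full 8-bit range
#'
#' Remaps intensities by \eqn{h = (g - GreyMin) \cdot E_f} with
#' \eqn{E_f = 255 / (GreyMax - GreyMin)}, rounded half-up, so the output
#' spans 0-255 while preserving the relative ordering (and, up to scale,
#' the distribution shape) of the input intensities. A constant image has
#' no dynamic range to stretch and is returned unchanged with a warning.
#'
#' @param img Grey image matrix.
#' @return Stretched grey image matrix.
#' @export
contrast_stretch <- function(img) {
  assert_grey_image(img)
  gmin <- min(img); gmax <- max(img)
  if (gmax == gmin) {
    warning("constant image: degenerate dynamic range, returning input unchanged",
            call. = FALSE)
    return(img)
  }
  clamp(round_half_up((img - gmin) * (255 / (gmax - gmin))), 0, 255)
}

#' Histogram equalisation
#'
#' Remaps every intensity level `n` to
#' \eqn{\mathrm{round}((L - 1) \, cdf(n))}, flattening the intensity
#' distribution so that contrast is concentrated where pixels are most
#' numerous. The mapping is monotone non-decreasing and the maximum observed
#' intensity always maps to `L - 1`.
#'
#' @param img Grey image matrix.
#' @param L Number of output levels (default 256).
#' @return Equalised grey image matrix with values in `[0, L - 1]`.
#' @export
equalize_histogram <- function(img, L = 256L) {
  h <- intensity_histogram(img, L)
  out <- matrix(h$bhist[as.integer(img) + 1L], nrow(img), ncol(img))
  out
}
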