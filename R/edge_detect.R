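# Edge detection: Sobel-type gradients, orientation-quantised non-maximum
# suppression, double-threshold hysteresis, and reduction of the edge map
# to the tube's two longest bounding edges.

#' 3x3 neighbourhood labelling
#'
#' Returns the mapping from labels `P1..P9` to `(row, column)` offsets.
#' `P1` is the centre; `P2..P9` run clockwise from North:
#' \preformatted{ P9 P2 P3
#'  P8 P1 P4
#'  P7 P6 P5 }
#' Opposite labels (`P2`/`P6`, `P3`/`P7`, `P4`/`P8`, `P5`/`P9`) are
#' point-symmetric about the centre, which is what the non-maximum
#' suppression pixel triples rely on.
#'
#' @return Named list of length-2 integer offsets `(drow, dcol)`.
#' @export
neighbourhood_key <- function() {
  list(
    P1 = c(0L, 0L),
    P2 = c(-1L, 0L), P3 = c(-1L, 1L), P4 = c(0L, 1L), P5 = c(1L, 1L),
    P6 = c(1L, 0L), P7 = c(1L, -1L), P8 = c(0L, -1L), P9 = c(-1L, -1L)
  )
}

sobel_kernels <- function(kernel = c("default", "classical")) {
  kernel <- match.arg(kernel)
  if (kernel == "default") {
    Kx <- rbind(c(-2, 0, 2), c(-3, 0, 3), c(-2, 0, 2))
  } else {
    Kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  }
  list(Kx = Kx, Ky = t(Kx))
}

correlate3x3 <- function(img, K) {
  p <- pad_reflect101(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in 1:3) for (j in 1:3) {
    if (K[i, j] == 0) next
    out <- out + K[i, j] * p[seq.int(i, nr + i - 1L), seq.int(j, nc + j - 1L)]
  }
  out
}

#' Image gradients from the Sobel-type operator pair
#'
#' Computes the two directional derivative responses `Ix` (along columns)
#' and `Iy` (along rows), the gradient magnitude
#' \eqn{|I| = \sqrt{I_x^2 + I_y^2}} and the gradient orientation. The
#' default kernels carry centre-row weight 3 and outer-row weight 2
#' (`X = [-2 0 2; -3 0 3; -2 0 2]`, `Y` its transpose); `kernel =
#' "classical"` substitutes the familiar 1-2-1 Sobel pair for comparison.
#'
#' Orientation `theta` is a bearing in degrees, measured clockwise from
#' "North" (the negative row direction), in `[0, 360)`: a gradient pointing
#' rightward (increasing column) has `theta = 90`. It is `NA` where the
#' magnitude is zero. Borders use reflect-101 padding.
#'
#' @param img Grey image matrix, at least 3x3.
#' @param kernel `"default"` (the 2-3-2 weighting) or `"classical"` (1-2-1).
#' @return Object of class `gradient_field`: list with matrices `Ix`, `Iy`,
#'   `magnitude`, `theta`.
#' @export
sobel_gradients <- function(img, kernel = c("default", "classical")) {
  assert_grey_image(img)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3x3 for the Sobel pass", call. = FALSE)
  k <- sobel_kernels(kernel)
  Ix <- correlate3x3(img, k$Kx)
  Iy <- correlate3x3(img, k$Ky)
  mag <- sqrt(Ix^2 + Iy^2)
  theta <- (atan2(Ix, -Iy) * 180 / pi) %% 360
  theta[mag == 0] <- NA_real_
  structure(list(Ix = Ix, Iy = Iy, magnitude = mag, theta = theta),
            class = "gradient_field")
}

#' Quantise a gradient bearing to intercardinal precision
#'
#' Rounds a bearing (degrees clockwise from North, `[0, 360)`) to one of
#' `{0, 45, 90, 135}` and returns the pixel triple whose outer two members
#' lie along the quantised gradient direction, for use by non-maximum
#' suppression:
#' \tabular{lll}{
#'   bearing near 0 or 180 \tab 0 \tab `P2, P1, P6` (North-South) \cr
#'   bearing near 45 or 225 \tab 45 \tab `P7, P1, P3` (SW-NE) \cr
#'   bearing near 90 or 270 \tab 90 \tab `P8, P1, P4` (West-East) \cr
#'   bearing near 135 or 315 \tab 135 \tab `P9, P1, P5` (NW-SE)
#' }
#' Interval endpoints (22.5, 67.5, ...) are assigned to the higher bucket,
#' deterministically.
#'
#' @param theta Numeric vector of bearings in `[0, 360)`.
#' @return List with `angle` (same length as `theta`) and `pixels`
#'   (character matrix, one `P`-label triple per row).
#' @export
quantize_orientation <- function(theta) {
  if (any(!is.na(theta) & (theta < 0 | theta >= 360)))
    stop("`theta` must lie in [0, 360)", call. = FALSE)
  a <- theta %% 180
  angle <- rep(NA_real_, length(a))
  angle[!is.na(a) & (a < 22.5 | a >= 157.5)] <- 0
  angle[!is.na(a) & a >= 22.5 & a < 67.5] <- 45
  angle[!is.na(a) & a >= 67.5 & a < 112.5] <- 90
  angle[!is.na(a) & a >= 112.5 & a < 157.5] <- 135
  triples <- rbind(`0` = c("P2", "P1", "P6"), `45` = c("P7", "P1", "P3"),
                   `90` = c("P8", "P1", "P4"), `135` = c("P9", "P1", "P5"))
  px <- matrix(NA_character_, length(angle), 3L)
  ok <- !is.na(angle)
  px[ok, ] <- triples[as.character(angle[ok]), , drop = FALSE]
  list(angle = angle, pixels = px)
}

# Offsets of the two comparison neighbours per quantised angle.
nms_offsets <- list(
  `0` = list(c(-1L, 0L), c(1L, 0L)),   # P2, P6
  `45` = list(c(1L, -1L), c(-1L, 1L)), # P7, P3
  `90` = list(c(0L, -1L), c(0L, 1L)),  # P8, P4
  `135` = list(c(-1L, -1L), c(1L, 1L)) # P9, P5
)

#' Non-maximum suppression along the quantised gradient direction
#'
#' A pixel survives if its gradient magnitude is `>=` the magnitudes of both
#' neighbours named by its orientation triple (so plateaus of equal
#' magnitude survive rather than being erased); every other pixel is set to
#' zero. Neighbours beyond the image border count as zero.
#'
#' @param field A `gradient_field` from [sobel_gradients()].
#' @return Matrix of suppressed gradient magnitudes (zeros elsewhere).
#' @export
nonmax_suppress <- function(field) {
  if (!inherits(field, "gradient_field"))
    stop("`field` must be a gradient_field", call. = FALSE)
  mag <- field$magnitude
  ang <- quantize_orientation(field$theta)$angle
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (b in names(nms_offsets)) {
    sel <- !is.na(ang) & ang == as.numeric(b)
    if (!any(sel)) next
    o <- nms_offsets[[b]]
    n1 <- shift_matrix(mag, o[[1]][1], o[[1]][2])
    n2 <- shift_matrix(mag, o[[2]][1], o[[2]][2])
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  out <- matrix(0, nrow(mag), ncol(mag))
  out[keep] <- mag[keep]
  out
}

#' Double-threshold hysteresis binarisation
#'
#' Classifies the suppressed gradient map against two thresholds
#' `z1 < z2`: pixels above `z2` are edges; pixels below `z1` are not;
#' pixels in `[z1, z2]` are edges exactly when they are connected to some
#' above-`z2` pixel through a path of non-zero pixels (8-connectivity).
#' The connectivity scan is a deterministic breadth-first search; since
#' connectivity is order-independent, the accept/reject decision does not
#' depend on the scan order.
#'
#' @param suppressed Non-negative magnitude matrix from [nonmax_suppress()].
#' @param z1,z2 Thresholds with `0 <= z1 < z2`.
#' @return Binary image (0/1 matrix) of edge pixels.
#' @export
hysteresis_binarize <- function(suppressed, z1, z2) {
  if (!is.matrix(suppressed) || any(suppressed < 0))
    stop("`suppressed` must be a non-negative matrix", call. = FALSE)
  if (!(z1 >= 0 && z1 < z2))
    stop("thresholds must satisfy 0 <= z1 < z2", call. = FALSE)
  nz <- suppressed > 0
  out <- matrix(0, nrow(suppressed), ncol(suppressed))
  if (!any(nz)) return(out)
  strong <- suppressed > z2
  if (!any(strong)) return(out)
  lab <- cpp_label_components(nz)
  keep_ids <- unique(lab[strong])
  out[nz & (suppressed >= z1) & matrix(lab %in% keep_ids, nrow(lab))] <- 1
  out
}

#' Connected edge components
#'
#' Splits a binary edge map into its 8-connected components of 1-valued
#' pixels, sorted by pixel count descending; ties are broken by the
#' smallest row-major starting coordinate, so the order is deterministic.
#'
#' @param edges Binary image.
#' @return Object of class `edge_components`: list of components, each a
#'   list with `pixels` (n x 2 matrix of `(row, col)`, row-major order) and
#'   `length` (pixel count); the image dimension is kept in attribute `dim`.
#' @export
extract_components <- function(edges) {
  assert_binary_image(edges, "edges")
  lab <- cpp_label_components(edges > 0)
  n <- max(lab)
  comps <- vector("list", n)
  if (n > 0) {
    for (k in seq_len(n)) {
      px <- which(lab == k, arr.ind = TRUE)
      px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
      dimnames(px) <- list(NULL, c("row", "col"))
      comps[[k]] <- structure(list(pixels = px, length = nrow(px)),
                              class = "edge_component")
    }
    start_key <- vapply(comps, function(co)
      (co$pixels[1, 1] - 1) * ncol(edges) + co$pixels[1, 2], numeric(1))
    len <- vapply(comps, `[[`, numeric(1), "length")
    comps <- comps[order(-len, start_key)]
  }
  structure(comps, dim_image = dim(edges), class = "edge_components")
}

#' Keep only the two longest edge components
#'
#' The tube's two bounding edges are assumed to be the two most extended
#' components of the edge map; all shorter components (noise, specks,
#' spurious inner edges) are deleted. When automatic selection picks the
#' wrong pair, `keep` manually overrides it with explicit component indices
#' (positions in the sorted component list).
#'
#' @param components An `edge_components` object from [extract_components()].
#' @param keep Optional integer vector of component indices to keep instead
#'   of the automatic two-longest choice.
#' @return Binary image containing only the kept components' pixels.
#' @export
keep_longest_two <- function(components, keep = NULL) {
  if (!inherits(components, "edge_components"))
    stop("`components` must come from extract_components()", call. = FALSE)
  dm <- attr(components, "dim_image")
  if (is.null(keep)) {
    if (length(components) < 2L)
      stop("fewer than two edge components detected; ",
           "lower the hysteresis thresholds (z1/z2) or check the input image",
           call. = FALSE)
    keep <- 1:2
  }
  if (any(keep < 1 | keep > length(components)))
    stop("`keep` indices out of range", call. = FALSE)
  out <- matrix(0, dm[1], dm[2])
  for (k in keep) out[components[[k]]$pixels] <- 1
  out
}
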