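# Width measurement: local centreline slope by finite differences, normal
# Bresenham rays walked to the silhouette contour, and the per-index
# diameter profile.

#' Local centreline slope by symmetric finite differences
#'
#' Estimates the slope at index `i` from the points `offset` indices to
#' either side: `(row[i-offset] - row[i+offset]) / (col[i-offset] -
#' col[i+offset])`. The wide stencil (default 4 to each side) averages out
#' pixel-level jitter of the rasterised line. A vertical tangent (zero
#' column difference) is flagged by returning `Inf` -- an explicitly
#' assigned sentinel, never the result of a floating-point division.
#'
#' @param line A `tube_centreline`.
#' @param i Index with `offset < i <= n - offset`.
#' @param offset Half-width of the stencil, `>= 1`.
#' @return Slope `drow/dcol` as a single number, or `Inf` for vertical.
#' @export
local_gradient <- function(line, i, offset = 4L) {
  stopifnot(inherits(line, "tube_centreline"))
  if (offset < 1L) stop("`offset` must be >= 1", call. = FALSE)
  if (i - offset < 1L || i + offset > line$n)
    stop("index too close to the line end for this offset", call. = FALSE)
  a <- line$points[i - offset, ]
  b <- line$points[i + offset, ]
  dx <- a[["col"]] - b[["col"]]
  dy <- a[["row"]] - b[["row"]]
  if (dx == 0) return(Inf)
  dy / dx
}

# Slope of the normal (negative reciprocal), with the vertical/horizontal
# sentinel handled explicitly.
normal_slope <- function(slope) {
  if (is.infinite(slope)) return(0)
  if (slope == 0) return(Inf)
  -1 / slope
}

#' Cast one normal ray from a centreline pixel to the silhouette contour
#'
#' Walks the Bresenham rasterisation of the line through `origin` whose
#' slope is the negative reciprocal of the centreline slope, in one of the
#' two opposite directions, and returns the last 1-valued pixel before the
#' first 0-valued pixel (or the border pixel if the ray leaves the image
#' while still inside the silhouette).
#'
#' @param silhouette Filled binary silhouette.
#' @param origin `(row, col)` of a silhouette pixel (value 1).
#' @param slope Local centreline slope (`Inf` for vertical), as returned by
#'   [local_gradient()].
#' @param direction `+1` or `-1`, selecting one of the two opposite rays.
#' @return Length-2 integer `(row, col)` of the ray's contour endpoint.
#' @export
cast_normal_ray <- function(silhouette, origin, slope, direction = 1L) {
  assert_binary_image(silhouette, "silhouette")
  cast_normal_ray_fast(silhouette, origin, slope, direction)
}

# Internal worker without the (O(n^2)-ish when repeated) input validation;
# walks the ray lazily in chunks so short rays never rasterise the full
# image diagonal. The pixel sequence is identical to
# bresenham_line(origin, far).
cast_normal_ray_fast <- function(silhouette, origin, slope, direction = 1L,
                                 chunk = 128L) {
  origin <- as.integer(origin)
  if (silhouette[origin[1], origin[2]] != 1)
    stop("ray origin is not inside the silhouette", call. = FALSE)
  ns <- normal_slope(slope)
  L <- nrow(silhouette) + ncol(silhouette)
  u <- if (is.infinite(ns)) c(1, 0) else c(ns, 1) / sqrt(1 + ns^2)
  far <- origin + round_half_up(direction * L * u)
  dr <- far[1] - origin[1]; dc <- far[2] - origin[2]
  adr <- abs(dr); adc <- abs(dc)
  sr <- sign(dr); sc <- sign(dc)
  nmaj <- max(adr, adc)
  nr <- nrow(silhouette); nc <- ncol(silhouette)
  prev <- origin
  k0 <- 0L
  while (k0 <= nmaj) {
    k <- k0:min(k0 + chunk - 1L, nmaj)
    if (adc >= adr) {
      col <- origin[2] + sc * k
      row <- origin[1] + sr * ((2L * k * adr + adc) %/% (2L * adc))
    } else {
      row <- origin[1] + sr * k
      col <- origin[2] + sc * ((2L * k * adc + adr) %/% (2L * adr))
    }
    inside <- row >= 1L & row <= nr & col >= 1L & col <= nc
    cut <- which(!inside)
    if (length(cut)) {
      if (cut[1] == 1L) return(prev)
      row <- row[seq_len(cut[1] - 1L)]
      col <- col[seq_len(cut[1] - 1L)]
    }
    vals <- silhouette[cbind(row, col)]
    z <- which(vals == 0)
    if (length(z)) {
      return(if (z[1] == 1L) prev
             else as.integer(c(row[z[1] - 1L], col[z[1] - 1L])))
    }
    prev <- as.integer(c(row[length(row)], col[length(col)]))
    if (length(cut)) return(prev)
    k0 <- k0 + chunk
  }
  prev
}

#' Diameter at one centreline index
#'
#' Casts the two opposite normal rays from the centreline pixel and
#' returns the Euclidean distance between their contour endpoints,
#' \eqn{d_i = \sqrt{(x_{i,1} - x_{i,2})^2 + (y_{i,1} - y_{i,2})^2}}
#' (coordinate differences -- a sum inside the squares could not satisfy
#' \eqn{d(p, p) = 0}). Near the line ends the finite-difference offset is
#' shrunk symmetrically to the largest feasible value `>= 1`.
#'
#' @param silhouette Filled binary silhouette.
#' @param line A `tube_centreline` inside it.
#' @param i Centreline index, `1 < i < n`.
#' @param offset Requested finite-difference half-distance (default 4).
#' @return A one-row data.frame: `index`, `row`, `col`, `slope`,
#'   `end1_row`, `end1_col`, `end2_row`, `end2_col`, `diameter_px`.
#' @export
diameter_at <- function(silhouette, line, i, offset = 4L) {
  stopifnot(inherits(line, "tube_centreline"))
  o <- min(offset, i - 1L, line$n - i)
  if (o < 1L)
    stop("index at the very end of the line: no slope stencil fits", call. = FALSE)
  s <- local_gradient(line, i, o)
  org <- line$points[i, ]
  e1 <- cast_normal_ray(silhouette, org, s, 1L)
  e2 <- cast_normal_ray(silhouette, org, s, -1L)
  data.frame(index = i, row = org[["row"]], col = org[["col"]],
             slope = unname(s),
             end1_row = e1[1], end1_col = e1[2],
             end2_row = e2[1], end2_col = e2[2],
             diameter_px = sqrt(sum((e1 - e2)^2)))
}

#' Diameter profile along the whole centreline
#'
#' Measures the diameter at every computable centreline index (all but the
#' two extreme points, where no slope stencil fits) and marks the valid
#' domain: thinning initiation makes the measurements near the two line
#' ends unreliable, so `trim` indices are excluded at each end. Summary
#' statistics from [summary.tube_profile()] are reported both over the full
#' range and over the valid domain.
#'
#' @param silhouette Filled binary silhouette.
#' @param line A `tube_centreline` inside it.
#' @param trim Indices excluded at each end of the valid domain
#'   (default 75, matching a 500-pixel-scale frame; scale with the image).
#' @param offset Finite-difference half-distance for the local slope.
#' @param pixels_per_mm Optional calibration factor; adds a `diameter_mm`
#'   column (see [calibrate()]).
#' @return Object of class `tube_profile`: a data.frame of per-index
#'   records (see [diameter_at()]) with attributes `valid_domain`
#'   (inclusive index range) and `trim`.
#' @export
width_profile <- function(silhouette, line, trim = 75L, offset = 4L,
                          pixels_per_mm = NULL) {
  stopifnot(inherits(line, "tube_centreline"))
  if (trim < 0) stop("`trim` must be >= 0", call. = FALSE)
  n <- line$n
  if (n < 3L) stop("centreline too short to profile", call. = FALSE)
  lo <- trim + 1L
  hi <- n - trim
  if (lo > hi)
    stop("valid domain is empty: `trim` removes the whole line; lower it",
         call. = FALSE)
  idx <- seq.int(2L, n - 1L)
  m <- length(idx)
  slope_v <- numeric(m)
  e1 <- matrix(NA_integer_, m, 2); e2 <- matrix(NA_integer_, m, 2)
  ok <- logical(m)
  pts <- line$points
  for (k in seq_len(m)) {
    i <- idx[k]
    o <- min(offset, i - 1L, n - i)
    a <- pts[i - o, ]; b <- pts[i + o, ]
    dx <- a[["col"]] - b[["col"]]
    s <- if (dx == 0) Inf else (a[["row"]] - b[["row"]]) / dx
    res <- tryCatch({
      p1 <- cast_normal_ray_fast(silhouette, pts[i, ], s, 1L)
      p2 <- cast_normal_ray_fast(silhouette, pts[i, ], s, -1L)
      list(p1, p2)
    }, error = function(e) NULL)
    if (is.null(res)) next
    slope_v[k] <- s
    e1[k, ] <- res[[1]]; e2[k, ] <- res[[2]]
    ok[k] <- TRUE
  }
  prof <- data.frame(
    index = idx[ok],
    row = pts[idx[ok], "row"], col = pts[idx[ok], "col"],
    slope = slope_v[ok],
    end1_row = e1[ok, 1], end1_col = e1[ok, 2],
    end2_row = e2[ok, 1], end2_col = e2[ok, 2],
    diameter_px = sqrt((e1[ok, 1] - e2[ok, 1])^2 + (e1[ok, 2] - e2[ok, 2])^2)
  )
  rownames(prof) <- NULL
  structure(prof,
            valid_domain = c(lo, hi),
            trim = as.integer(trim),
            class = c("tube_profile", "data.frame")) -> out
  if (!is.null(pixels_per_mm)) out <- calibrate(out, pixels_per_mm)
  out
}

#' Convert a pixel profile to millimetres
#'
#' Divides every diameter by the `pixels_per_mm` calibration factor
#' (obtained from an in-image reference of known physical size) and stores
#' the result in a `diameter_mm` column.
#'
#' @param profile A `tube_profile`.
#' @param pixels_per_mm Positive scalar, pixels per millimetre.
#' @return The profile with a `diameter_mm` column and a `pixels_per_mm`
#'   attribute.
#' @export
calibrate <- function(profile, pixels_per_mm) {
  stopifnot(inherits(profile, "tube_profile"))
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      pixels_per_mm <= 0)
    stop("`pixels_per_mm` must be a positive scalar", call. = FALSE)
  profile$diameter_mm <- profile$diameter_px / pixels_per_mm
  attr(profile, "pixels_per_mm") <- pixels_per_mm
  profile
}

#' @export
summary.tube_profile <- function(object, ...) {
  vd <- attr(object, "valid_domain")
  valid <- object$index >= vd[1] & object$index <= vd[2]
  out <- list(
    n_indices = nrow(object),
    valid_domain = vd,
    mean_full = mean(object$diameter_px),
    sd_full = sd(object$diameter_px),
    mean_valid = mean(object$diameter_px[valid]),
    sd_valid = sd(object$diameter_px[valid]),
    pixels_per_mm = attr(object, "pixels_per_mm")
  )
  class(out) <- "summary.tube_profile"
  out
}

#' @export
print.summary.tube_profile <- function(x, ...) {
  cat(sprintf("Diameter profile: %d indices, valid domain [%d, %d]\n",
              x$n_indices, x$valid_domain[1], x$valid_domain[2]))
  cat(sprintf("  mean +/- SD (valid domain): %.2f +/- %.2f px\n",
              x$mean_valid, x$sd_valid))
  cat(sprintf("  mean +/- SD (all indices):  %.2f +/- %.2f px\n",
              x$mean_full, x$sd_full))
  if (!is.null(x$pixels_per_mm))
    cat(sprintf("  calibration: %.3g px/mm -> mean %.3f mm\n",
                x$pixels_per_mm, x$mean_valid / x$pixels_per_mm))
  invisible(x)
}

#' Write a diameter profile as CSV
#'
#' Columns: `index,row,col,end1_row,end1_col,end2_row,end2_col,diameter_px`
#' and, when calibrated, `diameter_mm`. Coordinates are 1-based
#' `(row, col)` with the row axis growing downward.
#'
#' @param profile A `tube_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "tube_profile"))
  cols <- c("index", "row", "col", "end1_row", "end1_col",
            "end2_row", "end2_col", "diameter_px")
  if ("diameter_mm" %in% names(profile)) cols <- c(cols, "diameter_mm")
  write.csv(as.data.frame(profile)[, cols], path, row.names = FALSE)
  invisible(path)
}
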