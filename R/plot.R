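# Base-graphics views of profiles and runs.

#' Plot a diameter profile
#'
#' Diameter in pixels against centreline index, with the valid domain
#' shaded and its mean drawn as a horizontal line.
#'
#' @param x A `tube_profile`.
#' @param truth Optional true width (scalar or vector over indices) drawn
#'   as a reference line.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tube_profile <- function(x, truth = NULL, ...) {
  vd <- attr(x, "valid_domain")
  graphics::plot(x$index, x$diameter_px, type = "l", col = "grey40",
                 xlab = "centreline index", ylab = "diameter (px)", ...)
  graphics::rect(vd[1], graphics::par("usr")[3], vd[2],
                 graphics::par("usr")[4],
                 col = grDevices::adjustcolor("steelblue", 0.10), border = NA)
  s <- summary(x)
  graphics::abline(h = s$mean_valid, col = "steelblue", lwd = 2)
  if (!is.null(truth))
    graphics::lines(x$index, rep_len(truth, nrow(x)), col = "firebrick",
                    lty = 2)
  invisible(x)
}

#' Overlay the centreline and sampled normals on the source image
#'
#' @param run A `tube_run`.
#' @param image Optional background grey image (defaults to the silhouette).
#' @param every Draw one normal ray every `every` indices (default 25).
#' @return `run`, invisibly.
#' @export
plot_overlay <- function(run, image = NULL, every = 25L) {
  stopifnot(inherits(run, "tube_run"))
  bg <- if (is.null(image)) run$silhouette * 255 else image
  nr <- nrow(bg); nc <- ncol(bg)
  graphics::plot(NA, xlim = c(1, nc), ylim = c(nr, 1), asp = 1,
                 xlab = "col", ylab = "row")
  graphics::rasterImage(grDevices::as.raster(bg / 255), 1, nr, nc, 1)
  pts <- run$centreline$points
  graphics::lines(pts[, "col"], pts[, "row"], col = "firebrick", lwd = 1)
  p <- run$profile
  sel <- p$index %% every == 0
  graphics::segments(p$end1_col[sel], p$end1_row[sel],
                     p$end2_col[sel], p$end2_row[sel],
                     col = grDevices::adjustcolor("steelblue", 0.7))
  invisible(run)
}
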