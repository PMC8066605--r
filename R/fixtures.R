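# Synthetic phantom tubes with analytic ground truth. These drive every
# validation in the package: straight inclined bands, annulus arcs and
# varying-width tubes, in positive (bright tube on dark) and negative
# polarity, plus controlled degradation (edge gaps, intensity noise).

#' Specification of a synthetic tube fixture
#'
#' @param kind `"straight"` (a band of constant perpendicular width
#'   crossing the frame at an incline), `"arc"` (an annulus sector centred
#'   on the frame's top-left corner) or `"varying"` (a straight-axis band
#'   whose width varies along the axis).
#' @param width True perpendicular width in pixels (for `"varying"`, the
#'   reference width passed to `width_function`).
#' @param angle Incline of the straight band in degrees from horizontal.
#' @param outer_radius Outer radius of the arc in pixels; the inner radius
#'   is `outer_radius - width`.
#' @param frame Square frame side in pixels.
#' @param polarity `"positive"` (tube 255 on background 0) or `"negative"`
#'   (the exact intensity complement).
#' @param width_function For `"varying"`: a function of the along-axis
#'   coordinate `s` (pixels, 0 at the frame centre) returning the local
#'   width.
#' @return Object of class `tube_spec`.
#' @export
tube_spec <- function(kind = c("straight", "arc", "varying"),
                      width = 100, angle = 10, outer_radius = 500,
                      frame = 500, polarity = c("positive", "negative"),
                      width_function = NULL) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (frame < 2) stop("`frame` must be >= 2", call. = FALSE)
  if (kind == "arc" && outer_radius <= width)
    stop("`outer_radius` must exceed `width` for an arc", call. = FALSE)
  if (kind == "varying" && !is.function(width_function))
    stop("`width_function` must be a function for kind = \"varying\"",
         call. = FALSE)
  if (kind == "straight" && frame < width)
    stop("`frame` too small to contain the band", call. = FALSE)
  structure(list(kind = kind, width = width, angle = angle,
                 outer_radius = outer_radius, frame = frame,
                 polarity = polarity, width_function = width_function),
            class = "tube_spec")
}

#' Render a control image with its analytic ground truth
#'
#' Renders the tube of a [tube_spec()] as an anti-alias-free binary-contrast
#' grey image (255/0, complemented for negative polarity) and returns the
#' exact width along the tube axis:
#' \itemize{
#'   \item straight: a band of perpendicular width `width` whose axis
#'     passes through the frame centre at `angle` degrees; a pixel is
#'     foreground when its centre lies within `width/2` of the axis.
#'   \item arc: an annulus `outer_radius - width <= rho <= outer_radius`
#'     about the top-left corner pixel; the radial thickness -- the width
#'     along every centreline normal -- is `width`.
#'   \item varying: like straight, with the local half-width
#'     `width_function(s) / 2` evaluated at the along-axis coordinate.
#' }
#'
#' @param spec A `tube_spec`.
#' @return Object of class `tube_fixture`: list with `image` (grey matrix),
#'   `truth` (data.frame `arclength_index`, `true_width_px`, sampled at
#'   integer arclengths along the axis) and `spec`.
#' @export
make_control_image <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  f <- spec$frame
  r <- matrix(seq_len(f), f, f)
  c_ <- matrix(seq_len(f), f, f, byrow = TRUE)
  ctr <- (f + 1) / 2
  if (spec$kind == "straight") {
    a <- spec$angle * pi / 180
    dist <- (r - ctr) * cos(a) + (c_ - ctr) * sin(a)
    fg <- abs(dist) <= spec$width / 2
    L <- ceiling(f / max(cos(a), sin(a)))
    truth <- data.frame(arclength_index = seq_len(L),
                        true_width_px = spec$width)
  } else if (spec$kind == "arc") {
    rho <- sqrt((r - 1)^2 + (c_ - 1)^2)
    fg <- rho >= (spec$outer_radius - spec$width) & rho <= spec$outer_radius
    rm <- spec$outer_radius - spec$width / 2
    L <- ceiling(rm * pi / 2)
    truth <- data.frame(arclength_index = seq_len(L),
                        true_width_px = spec$width)
  } else {
    a <- spec$angle * pi / 180
    dist <- (r - ctr) * cos(a) + (c_ - ctr) * sin(a)
    s <- (c_ - ctr) * cos(a) - (r - ctr) * sin(a)
    w <- matrix(spec$width_function(as.numeric(s)), f, f)
    fg <- abs(dist) <= w / 2
    smax <- ceiling(f / max(cos(a), sin(a)) / 2)
    ss <- seq.int(-smax, smax)
    truth <- data.frame(arclength_index = ss,
                        true_width_px = spec$width_function(ss))
  }
  img <- matrix(0, f, f)
  img[fg] <- 255
  if (spec$polarity == "negative") img <- 255 - img
  structure(list(image = img, truth = truth, spec = spec),
            class = "tube_fixture")
}

#' The four standard control images
#'
#' Convenience wrapper for the validation set: `"A"`/`"B"` are positive/
#' negative straight 100-pixel-wide bands at a 10 degree incline, `"C"`/
#' `"D"` positive/negative 100-pixel-wide annulus arcs of 500-pixel outer
#' radius, all in a 500x500 frame.
#'
#' @param which One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param frame Frame size (default 500); other lengths scale with it.
#' @return A `tube_fixture`.
#' @export
control_image <- function(which = c("A", "B", "C", "D"), frame = 500) {
  which <- match.arg(which)
  scale <- frame / 500
  spec <- switch(which,
    A = tube_spec("straight", width = 100 * scale, angle = 10, frame = frame,
                  polarity = "positive"),
    B = tube_spec("straight", width = 100 * scale, angle = 10, frame = frame,
                  polarity = "negative"),
    C = tube_spec("arc", width = 100 * scale, outer_radius = 500 * scale,
                  frame = frame, polarity = "positive"),
    D = tube_spec("arc", width = 100 * scale, outer_radius = 500 * scale,
                  frame = frame, polarity = "negative")
  )
  make_control_image(spec)
}

#' Re-render a fixture at a different frame size
#'
#' All lengths (width, radius) are scaled by `target_frame / frame` and the
#' tube re-rendered analytically -- no pixel resampling, so no
#' interpolation artefacts.
#'
#' @param spec A `tube_spec`.
#' @param target_frame New frame side in pixels, `>= 100`.
#' @return A `tube_fixture` at the new scale.
#' @export
rescale_fixture <- function(spec, target_frame) {
  stopifnot(inherits(spec, "tube_spec"))
  if (target_frame < 100) stop("`target_frame` must be >= 100", call. = FALSE)
  k <- target_frame / spec$frame
  spec2 <- spec
  spec2$frame <- target_frame
  spec2$width <- spec$width * k
  spec2$outer_radius <- spec$outer_radius * k
  make_control_image(spec2)
}

#' Degrade an image with edge gaps and/or intensity noise
#'
#' Reproducible (seeded) degradation for robustness testing:
#' \itemize{
#'   \item `gaps` (binary edge maps only): punches `n` gaps into the edge
#'     curves. Each gap removes one edge's pixels over a run of consecutive
#'     scan lines whose length is `1 + rgeom(prob)` -- geometric with
#'     median 1 pixel at the default `prob = 0.5`.
#'   \item `noise` (grey images): adds Gaussian intensity noise with the
#'     given `sd` and an optional linear background `gradient` (peak
#'     amplitude in levels), then clamps back to `[0, 255]`.
#' }
#' With neither requested the input is returned unchanged.
#'
#' @param img Binary edge map (for `gaps`) or grey image (for `noise`).
#' @param gaps `NULL`, a count, or a list with `n` and `prob`.
#' @param noise `NULL` or a list with `sd` and optional `gradient`.
#' @param seed Integer seed; required when any randomness is requested.
#' @return Degraded image of the same type and dimensions.
#' @export
degrade <- function(img, gaps = NULL, noise = NULL, seed = NULL) {
  if (is.null(gaps) && is.null(noise)) return(img)
  if (is.null(seed)) stop("`seed` is required for reproducible degradation",
                          call. = FALSE)
  set.seed(seed)
  out <- img
  if (!is.null(gaps)) {
    if (is.numeric(gaps)) gaps <- list(n = gaps)
    n <- gaps$n %||% 50L
    prob <- gaps$prob %||% 0.5
    assert_binary_image(out, "img")
    comps <- extract_components(out)
    if (!length(comps)) return(out)
    for (g in seq_len(n)) {
      k <- sample.int(length(comps), 1L)
      px <- comps[[k]]$pixels
      len <- 1L + stats::rgeom(1L, prob)
      # remove this component's pixels over `len` consecutive columns
      # (rows for near-vertical components). A gap is interior by
      # definition -- missing data within an edge, with detections on both
      # sides to interpolate between -- so the start position is drawn
      # away from the component's ends.
      vertical <- diff(range(px[, 1])) > diff(range(px[, 2]))
      axis <- if (vertical) 1L else 2L
      margin <- 10L
      lo_ax <- min(px[, axis]) + margin
      hi_ax <- max(px[, axis]) - margin - len + 1L
      if (hi_ax <= lo_ax) next
      start <- sample.int(hi_ax - lo_ax + 1L, 1L) + lo_ax - 1L
      hit <- px[, axis] >= start & px[, axis] <= start + len - 1L
      out[px[hit, , drop = FALSE]] <- 0
    }
  }
  if (!is.null(noise)) {
    assert_grey_image(out, "img")
    sd <- noise$sd %||% 0
    grad <- noise$gradient %||% 0
    nr <- nrow(out); nc <- ncol(out)
    ramp <- matrix(seq(0, grad, length.out = nc), nr, nc, byrow = TRUE)
    out <- clamp(round_half_up(out + ramp +
                                 matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)),
                 0, 255)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fixture set to disk
#'
#' Writes the rendered image as PNG, the ground truth as CSV
#' (`arclength_index,true_width_px`) and a small JSON manifest echoing the
#' spec, under a common prefix.
#'
#' @param fixture A `tube_fixture`.
#' @param prefix Path prefix (directories must exist).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture <- function(fixture, prefix) {
  stopifnot(inherits(fixture, "tube_fixture"))
  paths <- paste0(prefix, c(".png", "_truth.csv", "_manifest.json"))
  write_image_png(fixture$image, paths[1])
  write.csv(fixture$truth, paths[2], row.names = FALSE)
  sp <- fixture$spec
  sp$width_function <- if (is.null(sp$width_function)) NULL else
    paste(deparse(sp$width_function), collapse = " ")
  jsonlite::write_json(unclass(sp), paths[3], auto_unbox = TRUE, null = "null")
  invisible(paths)
}
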