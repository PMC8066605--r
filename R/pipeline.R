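# End-to-end orchestration: configuration object, the staged pipeline, and
# serialised outputs.

#' Pipeline configuration
#'
#' Collects every free parameter of the pipeline in one validated object.
#'
#' @param sigma Gaussian smoothing spread in pixels (default 2).
#' @param kernel_radius Smoothing kernel half-width (default
#'   `ceiling(3 * sigma)`).
#' @param use_equalization Apply histogram equalisation as the contrast
#'   stage? Default `FALSE`: the default contrast stage is the linear
#'   stretch, which is unbiased on any image; equalisation concentrates
#'   output contrast at the most populated intensity levels, which helps
#'   poorly-defined photographs but on high-contrast imagery relocates the
#'   dominant intensity jump away from the physical edge and biases the
#'   measured width (see the methods vignette). Set `TRUE` for
#'   low-contrast images.
#' @param z1_frac,z2_frac Hysteresis thresholds as fractions of the maximum
#'   suppressed gradient magnitude, `0 <= z1_frac < z2_frac <= 1`
#'   (defaults 0.08 and 0.20; fractions make the thresholds invariant to
#'   the image's absolute contrast).
#' @param gradient_offset Finite-difference half-distance for the local
#'   centreline slope (default 4).
#' @param end_trim Centreline indices excluded at each end of the valid
#'   domain (default 75 at the 500-pixel scale).
#' @param fill_combination `"intersection"` (default) or `"union"` of the
#'   column and row fill passes.
#' @param pixels_per_mm Optional calibration factor.
#' @param manual_edge_indices Optional manual override for the two edge
#'   components (see [keep_longest_two()]).
#' @param sobel_kernel `"default"` (the 2-3-2 weighting) or `"classical"` (1-2-1).
#' @param seed Optional integer seed echoed into outputs (the default
#'   pipeline is fully deterministic; the seed only matters for degraded
#'   fixtures generated alongside a run).
#' @param debug_dir Optional directory; when set, every intermediate stage
#'   is written there as a PNG together with the profile CSV and summary
#'   JSON.
#' @return Object of class `tube_config`.
#' @export
tube_config <- function(sigma = 2, kernel_radius = ceiling(3 * sigma),
                        use_equalization = FALSE,
                        z1_frac = 0.08, z2_frac = 0.20,
                        gradient_offset = 4L, end_trim = 75L,
                        fill_combination = c("intersection", "union"),
                        pixels_per_mm = NULL, manual_edge_indices = NULL,
                        sobel_kernel = c("default", "classical"),
                        seed = NULL, debug_dir = NULL) {
  fill_combination <- match.arg(fill_combination)
  sobel_kernel <- match.arg(sobel_kernel)
  if (!(z1_frac >= 0 && z1_frac < z2_frac && z2_frac <= 1))
    stop("need 0 <= z1_frac < z2_frac <= 1", call. = FALSE)
  if (gradient_offset < 1) stop("`gradient_offset` must be >= 1", call. = FALSE)
  if (end_trim < 0) stop("`end_trim` must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(list(sigma = sigma, kernel_radius = kernel_radius,
                 use_equalization = use_equalization,
                 z1_frac = z1_frac, z2_frac = z2_frac,
                 gradient_offset = as.integer(gradient_offset),
                 end_trim = as.integer(end_trim),
                 fill_combination = fill_combination,
                 pixels_per_mm = pixels_per_mm,
                 manual_edge_indices = manual_edge_indices,
                 sobel_kernel = sobel_kernel,
                 seed = seed, debug_dir = debug_dir),
            class = "tube_config")
}

#' Run the full diameter-estimation pipeline
#'
#' Executes, in order: greyscale conversion (3-channel inputs) -> Gaussian
#' smoothing -> contrast enhancement (linear stretch, or histogram
#' equalisation when `use_equalization`) -> Sobel gradients -> non-maximum
#' suppression -> hysteresis binarisation -> component extraction -> keep
#' the two longest edges -> silhouette fill -> Zhang-Suen thinning ->
#' secondary thinning -> centreline ordering -> width profile ->
#' (optional) millimetre calibration. Stage failures are re-raised with the
#' stage name and, where useful, a remediation hint. The default path has
#' no randomness: identical input and configuration give identical output.
#'
#' @param image A file path, a grey matrix, an RGB array, or a
#'   `tube_fixture`.
#' @param config A [tube_config()].
#' @param keep_stages Keep all intermediate images in the result? (Default
#'   `FALSE`; they are large.)
#' @return Object of class `tube_run`: list with `profile`
#'   (a [width_profile()] result), `centreline`, `silhouette`, `edges`,
#'   `summary`, `config`, `timing` (per-stage seconds) and, when requested,
#'   `stages`.
#' @export
run_pipeline <- function(image, config = tube_config(), keep_stages = FALSE) {
  stopifnot(inherits(config, "tube_config"))
  if (inherits(image, "tube_fixture")) image <- image$image
  if (is.character(image)) image <- read_image(image)

  timing <- c()
  stages <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timing[[name]] <<- proc.time()[["elapsed"]] - t0
    if (keep_stages || !is.null(config$debug_dir)) stages[[name]] <<- val
    val
  }

  grey <- if (length(dim(image)) == 3L)
    stage("to_grayscale", to_grayscale(image)) else
    stage("to_grayscale", assert_grey_image(image))
  smoothed <- stage("gaussian_smooth",
                    gaussian_smooth(grey, config$sigma, config$kernel_radius))
  enhanced <- stage("contrast",
                    if (config$use_equalization) equalize_histogram(smoothed)
                    else suppressWarnings(contrast_stretch(smoothed)))
  grad <- stage("sobel_gradients", sobel_gradients(enhanced, config$sobel_kernel))
  supp <- stage("nonmax_suppress", nonmax_suppress(grad))
  mx <- max(supp)
  edges <- stage("hysteresis_binarize",
                 hysteresis_binarize(supp, config$z1_frac * mx,
                                     config$z2_frac * mx))
  comps <- stage("extract_components", extract_components(edges))
  two <- stage("keep_longest_two",
               keep_longest_two(comps, keep = config$manual_edge_indices))
  sil <- stage("fill_silhouette",
               fill_silhouette(two, combine = config$fill_combination))
  skel <- stage("zhang_suen_thin", zhang_suen_thin(sil))
  skel2 <- stage("secondary_thin", secondary_thin(skel))
  line <- stage("order_centreline", order_centreline(skel2))
  prof <- stage("width_profile",
                width_profile(sil, line, trim = config$end_trim,
                              offset = config$gradient_offset,
                              pixels_per_mm = config$pixels_per_mm))

  run <- structure(list(
    profile = prof,
    centreline = line,
    silhouette = sil,
    edges = two,
    summary = c(unclass(summary(prof)), list(config = unclass(config))),
    config = config,
    timing = data.frame(stage = names(timing),
                        seconds = round(unlist(timing), 4),
                        row.names = NULL),
    stages = if (keep_stages) stages else NULL
  ), class = "tube_run")

  if (!is.null(config$debug_dir)) {
    dir.create(config$debug_dir, showWarnings = FALSE, recursive = TRUE)
    dd <- config$debug_dir
    write_image_png(stages$gaussian_smooth, file.path(dd, "01_smoothed.png"))
    write_image_png(stages$contrast, file.path(dd, "02_enhanced.png"))
    m <- stages$sobel_gradients$magnitude
    write_image_png(m / max(m, 1) * 255, file.path(dd, "03_sobel_magnitude.png"))
    write_image_png(stages$nonmax_suppress / max(stages$nonmax_suppress, 1) * 255,
                    file.path(dd, "04_suppressed.png"))
    write_image_png(stages$hysteresis_binarize * 255, file.path(dd, "05_edges.png"))
    write_image_png(two * 255, file.path(dd, "06_two_edges.png"))
    write_image_png(sil * 255, file.path(dd, "07_silhouette.png"))
    write_image_png(skel2 * 255, file.path(dd, "08_centreline.png"))
    write_profile_csv(prof, file.path(dd, "profile.csv"))
    jsonlite::write_json(run$summary, file.path(dd, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  run
}

#' @export
print.tube_run <- function(x, ...) {
  cat("<tube_run>\n")
  print(summary(x$profile))
  cat(sprintf("  total time: %.2f s over %d stages\n",
              sum(x$timing$seconds), nrow(x$timing)))
  invisible(x)
}
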