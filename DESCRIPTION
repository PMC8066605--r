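Package: tubewidth
Title: Automated Diameter Profiling of Tubular Structures in 2D Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures the diameter of an elongated biological tube (a blood
    vessel, a fallopian tube) at every point along its length from a single
    2D photograph. The pipeline converts the image to greyscale, smooths and
    contrast-enhances it, extracts the tube's two bounding edges with a
    Sobel-gradient edge detector (orientation-quantised non-maximum
    suppression and double-threshold hysteresis), fills the region between
    the two longest edges into a solid binary silhouette by scan-line
    interpolation, thins the silhouette to an ordered one-pixel centreline
    (Zhang-Suen thinning plus a secondary neighbour-count reduction), and
    casts integer Bresenham rays normal to the centreline to measure the
    local width in pixels (optionally calibrated to millimetres). A fixture
    generator renders straight, arc and varying-width phantom tubes with
    analytic ground truth so the whole pipeline can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
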