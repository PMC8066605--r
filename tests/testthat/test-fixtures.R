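test_that("straight fixtures render the exact band", {
  fx <- make_control_image(tube_spec("straight", width = 100, angle = 0,
                                     frame = 500))
  runs <- apply(fx$image, 2, function(v) sum(v > 0))
  expect_true(all(runs == 100))
  expect_setequal(unique(as.vector(fx$image)), c(0, 255))
  expect_true(all(fx$truth$true_width_px == 100))
})

test_that("arc fixtures have the stated radial thickness everywhere", {
  fx <- make_control_image(tube_spec("arc", width = 100, outer_radius = 500,
                                     frame = 500))
  img <- fx$image
  # brute-force radial scan at sampled angles, avoiding the frame-clipped
  # slivers hard against the two axes
  th <- seq(4, 86, length.out = 1000) * pi / 180
  for (t in th) {
    rho <- seq(350, 550, by = 0.25)
    px <- unique(cbind(round(rho * sin(t)) + 1, round(rho * cos(t)) + 1))
    px <- px[px[, 1] >= 1 & px[, 1] <= 500 & px[, 2] >= 1 & px[, 2] <= 500, ]
    fg <- px[img[px] > 0, , drop = FALSE]
    # radial extent between the centres of the first and last tube pixels:
    # the continuous annulus spans [400, 500] and the digitised ray loses
    # at most one sampling gap (up to sqrt(2) on diagonal rays) per rim
    d <- sqrt((fg[, 1] - 1)^2 + (fg[, 2] - 1)^2)
    expect_gt(max(d) - min(d), 100 - 2 * sqrt(2) - 1e-9)
    expect_lte(max(d) - min(d), 100 + 1e-9)
  }
})

test_that("negative polarity is the exact intensity complement", {
  for (pair in list(c("A", "B"), c("C", "D"))) {
    a <- control_image(pair[1])$image
    b <- control_image(pair[2])$image
    expect_equal(b, 255 - a)
  }
})

test_that("varying-width fixtures store the sampled width function", {
  wf <- function(s) 100 + 10 * sin(s / 50)
  fx <- make_control_image(tube_spec("varying", width = 100, angle = 0,
                                     frame = 300, width_function = wf))
  expect_equal(fx$truth$true_width_px, wf(fx$truth$arclength_index))
  # at angle 0 the filled run in column c has width wf(s(c)) within 1 px
  ctr <- (300 + 1) / 2
  runs <- apply(fx$image, 2, function(v) sum(v > 0))
  expect_true(all(abs(runs - wf(seq_len(300) - ctr)) <= 1))
})

test_that("degradation is reproducible and identity without gaps or noise", {
  run <- default_run("A")
  two <- run$edges
  expect_identical(degrade(two), two)
  g1 <- degrade(two, gaps = list(n = 20, prob = 0.5), seed = 7)
  g2 <- degrade(two, gaps = list(n = 20, prob = 0.5), seed = 7)
  expect_identical(g1, g2)
  g3 <- degrade(two, gaps = list(n = 20, prob = 0.5), seed = 8)
  expect_false(identical(g1, g3))
  expect_lt(sum(g1), sum(two))
  # noise degradation stays in range and is seeded
  img <- control_image("A")$image
  n1 <- degrade(img, noise = list(sd = 10, gradient = 30), seed = 3)
  expect_identical(n1, degrade(img, noise = list(sd = 10, gradient = 30),
                               seed = 3))
  expect_true(all(n1 >= 0 & n1 <= 255))
  expect_error(degrade(img, noise = list(sd = 5)), "seed")
})

test_that("rescaling re-renders analytically with proportional lengths", {
  sp <- tube_spec("straight", width = 100, angle = 0, frame = 500)
  expect_equal(rescale_fixture(sp, 500)$image, make_control_image(sp)$image)
  big <- rescale_fixture(sp, 1000)
  runs <- apply(big$image, 2, function(v) sum(v > 0))
  expect_true(all(runs == 200))
})

test_that("fixture files round-trip the ground truth losslessly", {
  fx <- make_control_image(tube_spec("straight", width = 60, angle = 5,
                                     frame = 200))
  pre <- file.path(tempdir(), "fix_test")
  paths <- write_fixture(fx, pre)
  truth <- utils::read.csv(paths[2])
  expect_equal(truth, fx$truth)
  img <- read_image(paths[1])
  expect_equal(img, fx$image)
  manifest <- jsonlite::read_json(paths[3])
  expect_equal(manifest$width, 60)
  unlink(paths)
})
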