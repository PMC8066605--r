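test_that("sobel gradients use the printed kernels and bearing convention", {
  expect_equal(max(sobel_gradients(matrix(80, 6, 6))$magnitude), 0)
  # horizontal ramp: one intensity step per column
  img <- matrix(rep(0:9, each = 10), 10, 10)
  g <- sobel_gradients(img)
  expect_true(all(g$Ix[3:8, 3:8] == 14))  # (2+3+2) * step of 2
  expect_true(all(g$Iy[3:8, 3:8] == 0))
  # gradient pointing East (Ix > 0, Iy = 0) is bearing 90
  expect_true(all(abs(g$theta[3:8, 3:8] - 90) < 1e-9))
  # vertical ramp: gradient along rows, bearing 180 (pointing "South")
  g2 <- sobel_gradients(t(img))
  expect_true(all(abs(g2$theta[3:8, 3:8] - 180) < 1e-9))
  expect_equal(g$magnitude^2, g$Ix^2 + g$Iy^2, tolerance = 1e-9)
  expect_error(sobel_gradients(matrix(1, 2, 5)), "3x3")
  # classical kernel option
  gc <- sobel_gradients(img, kernel = "classical")
  expect_true(all(gc$Ix[3:8, 3:8] == 8))
})

test_that("orientation quantisation matches the intercardinal bucket table", {
  q <- quantize_orientation(30)
  expect_equal(q$angle, 45)
  expect_equal(q$pixels[1, ], c("P7", "P1", "P3"))
  expect_equal(quantize_orientation(0)$pixels[1, ], c("P2", "P1", "P6"))
  expect_equal(quantize_orientation(90)$pixels[1, ], c("P8", "P1", "P4"))
  expect_equal(quantize_orientation(130)$angle, 135)
  # inclusive endpoints resolve to the higher bucket
  expect_equal(quantize_orientation(22.5)$angle, 45)
  expect_equal(quantize_orientation(157.5)$angle, 0)
  # total on [0,360) and periodic with period 180
  th <- seq(0, 359.75, by = 0.25)
  a <- quantize_orientation(th)$angle
  expect_false(anyNA(a))
  expect_equal(a, quantize_orientation((th + 180) %% 360)$angle)
  expect_error(quantize_orientation(400), "0, 360")
})

test_that("neighbourhood key covers the eight offsets with opposite pairs", {
  key <- neighbourhood_key()
  offs <- do.call(rbind, key[-1])
  expect_equal(nrow(unique(offs)), 8)
  for (pair in list(c("P2", "P6"), c("P3", "P7"), c("P4", "P8"), c("P5", "P9")))
    expect_equal(key[[pair[1]]], -key[[pair[2]]])
})

test_that("non-maximum suppression keeps ridge crests and plateaus", {
  field <- function(mag, theta) {
    structure(list(Ix = mag, Iy = mag, magnitude = mag,
                   theta = matrix(theta, nrow(mag), ncol(mag))),
              class = "gradient_field")
  }
  # ideal 1-px vertical ridge, gradient horizontal (bearing 90)
  m <- matrix(0, 7, 7); m[, 4] <- 5
  th <- matrix(NA_real_, 7, 7); th[, 4] <- 90
  out <- nonmax_suppress(field(m, 90))
  out[is.na(out)] <- 0
  expect_equal(out, m)
  # 3-px ridge with profile (1, 2, 1): only the centre column survives
  m2 <- matrix(0, 7, 7); m2[, 3] <- 1; m2[, 4] <- 2; m2[, 5] <- 1
  out2 <- nonmax_suppress(field(m2, 90))
  expect_equal(which(colSums(out2) > 0), 4L)
  # constant plateau: every pixel survives under the >= comparison
  m3 <- matrix(3, 5, 5)
  expect_equal(nonmax_suppress(field(m3, 90)), m3)
  # suppression never increases magnitude
  set.seed(5)
  mag <- matrix(stats::runif(100), 10, 10)
  fl <- sobel_gradients(matrix(sample(0:255, 100, TRUE), 10, 10))
  sup <- nonmax_suppress(fl)
  expect_true(all(sup <= fl$magnitude + 1e-12))
})

test_that("hysteresis follows the two thresholds and branch connectivity", {
  m <- matrix(0, 5, 5)
  m[3, 3] <- 11
  expect_equal(hysteresis_binarize(m, 5, 10)[3, 3], 1)
  m[3, 3] <- 4
  expect_equal(sum(hysteresis_binarize(m, 5, 10)), 0)
  # weak-weak-strong chain accepted; identical isolated weak chain rejected
  m2 <- matrix(0, 5, 7)
  m2[3, 1:2] <- 7; m2[3, 3] <- 12   # chain touching a strong pixel
  m2[1, 5:7] <- 7                   # isolated weak chain
  out <- hysteresis_binarize(m2, 5, 10)
  expect_equal(out[3, 1:3], c(1, 1, 1))
  expect_equal(sum(out[1, ]), 0)
  expect_error(hysteresis_binarize(m2, 10, 10), "z1 < z2")
  # sub-z1 pixels conduct connectivity but never become edges
  m3 <- matrix(0, 3, 5)
  m3[2, ] <- c(7, 2, 2, 7, 12)
  out3 <- hysteresis_binarize(m3, 5, 10)
  expect_equal(out3[2, ], c(1, 0, 0, 1, 1))
})

test_that("hysteresis equals the brute-force reachability oracle", {
  set.seed(42)
  for (k in 1:20) {
    supp <- matrix(0, 32, 32)
    nz <- matrix(stats::runif(32 * 32) < 0.25, 32, 32)
    supp[nz] <- stats::runif(sum(nz))
    z1 <- 0.3; z2 <- 0.7
    expect_equal(hysteresis_binarize(supp, z1, z2),
                 ref_hysteresis(supp, z1, z2))
  }
})

test_that("component extraction matches flood fill with deterministic ordering", {
  m <- matrix(0, 10, 20)
  m[2, 3:12] <- 1   # length 10
  m[7, 2:5] <- 1    # length 4
  comps <- extract_components(m)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, numeric(1), "length"), c(10, 4))
  expect_equal(extract_components(matrix(c(0, 0, 1, 0), 2, 2))[[1]]$length, 1)
  expect_length(extract_components(matrix(0, 4, 4)), 0)
  set.seed(9)
  for (k in 1:10) {
    m <- matrix(as.numeric(stats::runif(30 * 30) < 0.2), 30, 30)
    got <- extract_components(m)
    want <- ref_flood_components(m > 0)
    expect_length(got, length(want))
    key <- function(px) paste(px[, 1], px[, 2], collapse = ";")
    expect_setequal(vapply(got, function(co) key(co$pixels), ""),
                    vapply(want, key, ""))
  }
})

test_that("two longest edges are kept, with tie-break and manual override", {
  m <- matrix(0, 30, 120)
  m[5, 1:100] <- 1
  m[15, 1:90] <- 1
  m[25, 1:5] <- 1
  comps <- extract_components(m)
  out <- keep_longest_two(comps)
  expect_equal(sum(out), 190)
  expect_equal(sum(out[25, ]), 0)
  # exactly two components: identity
  m2 <- m; m2[25, ] <- 0
  expect_equal(keep_longest_two(extract_components(m2)), m2)
  # equal lengths: smallest row-major starting coordinates win
  m3 <- matrix(0, 40, 60)
  m3[10, 1:50] <- 1; m3[20, 1:50] <- 1; m3[30, 1:50] <- 1
  out3 <- keep_longest_two(extract_components(m3))
  expect_equal(sum(out3[10, ]), 50)
  expect_equal(sum(out3[20, ]), 50)
  expect_equal(sum(out3[30, ]), 0)
  # manual override picks explicit components
  out4 <- keep_longest_two(extract_components(m3), keep = c(1, 3))
  expect_equal(sum(out4[30, ]), 50)
  expect_error(keep_longest_two(extract_components(matrix(c(0, 1, 0, 0), 2))),
               "fewer than two")
})

test_that("the edge stage on a horizontal band yields its two flanking edges", {
  fx <- make_control_image(tube_spec("straight", width = 40, angle = 0,
                                     frame = 160))
  sm <- gaussian_smooth(fx$image)
  en <- suppressWarnings(contrast_stretch(sm))
  supp <- nonmax_suppress(sobel_gradients(en))
  edges <- hysteresis_binarize(supp, 0.08 * max(supp), 0.2 * max(supp))
  comps <- extract_components(edges)
  expect_length(comps, 2)
  mid <- (160 + 1) / 2
  rows1 <- comps[[1]]$pixels[, 1]; rows2 <- comps[[2]]$pixels[, 1]
  expect_true(all(rows1 < mid) || all(rows1 > mid))
  expect_true(all(rows2 < mid) || all(rows2 > mid))
  expect_true(xor(all(rows1 < mid), all(rows2 < mid)))
})
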