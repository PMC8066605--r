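test_that("to_grayscale averages channels and honours weights", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(30, 60, 90)
  img[1, 2, ] <- c(255, 0, 0)
  g <- to_grayscale(img)
  expect_equal(g[1, 1], 60)
  expect_equal(g[2, 1], 0)
  expect_equal(to_grayscale(img, weights = c(1, 0, 0))[1, 2], 255)
  # equal channels reproduce any single channel exactly
  set.seed(7)
  ch <- matrix(sample(0:255, 64, TRUE), 8, 8)
  rgb <- array(ch, c(8, 8, 3))
  expect_equal(to_grayscale(rgb), ch)
  expect_error(to_grayscale(ch), "3 channels")
  expect_error(to_grayscale(img, weights = c(0, 0, 0)), "positive")
})

test_that("gaussian kernel matches the scaled Gaussian and normalises", {
  k <- gaussian_kernel(sigma = 2, normalize = FALSE)
  expect_equal(k[attr(k, "radius") + 1, attr(k, "radius") + 1],
               1 / (2 * pi * 2^2))
  kn <- gaussian_kernel(sigma = 1.3, radius = 4)
  expect_equal(sum(kn), 1, tolerance = 1e-9)
  expect_equal(c(kn), c(kn[rev(seq_len(nrow(kn))), rev(seq_len(ncol(kn)))]))
  expect_error(gaussian_kernel(-1), "sigma")
})

test_that("gaussian smoothing preserves constants and matches direct convolution", {
  expect_equal(gaussian_smooth(matrix(97, 9, 9), sigma = 2),
               matrix(97, 9, 9))
  # unit impulse: compare against the naive convolution oracle
  img <- matrix(0, 15, 15); img[8, 8] <- 255
  got <- gaussian_smooth(img, sigma = 1.5, radius = 3)
  K <- gaussian_kernel(1.5, 3)
  want <- floor(ref_convolve(img, K) + 0.5)
  expect_equal(got, want)
  # impulse response symmetric: row sums equal column sums
  expect_equal(rowSums(got), colSums(got))
  # smoothing never widens the dynamic range
  set.seed(11)
  r <- matrix(sample(0:255, 20 * 20, TRUE), 20, 20)
  s <- gaussian_smooth(r, sigma = 2)
  expect_gte(min(s), min(r))
  expect_lte(max(s), max(r))
  expect_error(gaussian_smooth(r, sigma = 0), "sigma")
})

test_that("contrast stretch maps extrema to the full range with half-up rounding", {
  img <- matrix(c(50, 100, 150, 120), 2, 2)
  out <- contrast_stretch(img)
  expect_equal(out[img == 150], 255)
  expect_equal(out[img == 50], 0)
  expect_equal(out[img == 100], 128)  # 50 * 2.55 = 127.5, half-up
  full <- matrix(c(0, 255, 17, 99), 2, 2)
  expect_equal(contrast_stretch(full), full)
  expect_warning(out2 <- contrast_stretch(matrix(42, 3, 3)), "constant")
  expect_equal(out2, matrix(42, 3, 3))
})

test_that("histogram equalisation follows the cdf mapping", {
  expect_true(all(equalize_histogram(matrix(7, 4, 4)) == 255))
  img <- matrix(c(rep(10, 8), rep(20, 8)), 4, 4)
  expect_setequal(unique(as.vector(equalize_histogram(img))), c(128, 255))
  # a perfectly uniform 256-level image maps within 1 level of identity
  u <- matrix(0:255, 16, 16)
  eq <- equalize_histogram(u)
  expect_lte(max(abs(eq - u)), 1)
  h <- intensity_histogram(u)
  expect_true(all(diff(h$cdf) >= 0))
  expect_equal(h$cdf[256], 1, tolerance = 1e-9)
  expect_true(all(h$bhist >= 0 & h$bhist <= 255))
})

test_that("intensity remappings are monotone and equalisation flattens the cdf", {
  set.seed(21)
  for (k in 1:5) {
    img <- matrix(sample(0:255, 400, TRUE, prob = stats::runif(256)^2), 20, 20)
    for (f in list(contrast_stretch, equalize_histogram)) {
      out <- suppressWarnings(f(img))
      o <- order(as.vector(img))
      expect_true(all(diff(as.vector(out)[o]) >= 0))
    }
    ks_to_uniform <- function(x) {
      cdf <- cumsum(tabulate(as.integer(x) + 1L, 256)) / length(x)
      max(abs(cdf - (1:256) / 256))
    }
    expect_lte(ks_to_uniform(equalize_histogram(img)), ks_to_uniform(img) + 1e-9)
  }
})
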