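test_that("local gradient uses the symmetric stencil with a vertical flag", {
  diag_line <- as_centreline(cbind(1:20, 1:20))
  expect_equal(local_gradient(diag_line, 10), 1)
  horiz <- as_centreline(cbind(rep(5L, 20), 1:20))
  expect_equal(local_gradient(horiz, 10), 0)
  vert <- as_centreline(cbind(1:20, rep(5L, 20)))
  expect_identical(local_gradient(vert, 10), Inf)
  # digitised slope-2 line recovers slope 2 within rasterisation tolerance
  pts <- bresenham_line(c(1, 1), c(61, 31))
  line2 <- as_centreline(pts)
  for (i in seq(10, 20))
    expect_lt(abs(local_gradient(line2, i) - 2), 0.15)
  expect_error(local_gradient(diag_line, 2, offset = 4), "too close")
  expect_error(local_gradient(diag_line, 10, offset = 0), "offset")
})

test_that("normal rays walk to the contour and stop at the last 1-pixel", {
  sil <- matrix(0, 121, 31)
  sil[10:110, ] <- 1                       # bar 101 rows tall
  org <- c(60, 15)
  e1 <- cast_normal_ray(sil, org, slope = 0, direction = 1)
  e2 <- cast_normal_ray(sil, org, slope = 0, direction = -1)
  expect_equal(e1, c(110L, 15L))
  expect_equal(e2, c(10L, 15L))
  # endpoint's next pixel along the ray is background
  expect_equal(sil[111, 15], 0)
  # origin adjacent to the contour, ray pointing outward: immediate stop
  expect_equal(cast_normal_ray(sil, c(10, 15), slope = 0, direction = -1),
               c(10L, 15L))
  expect_error(cast_normal_ray(sil, c(5, 15), 0, 1), "not inside")
  # disc of radius 40: rays of any slope measure the radius, short by at
  # most one digitisation step (up to sqrt(2) on diagonal rays)
  rr <- matrix(1:101, 101, 101); cc <- t(rr)
  disc <- matrix(0, 101, 101)
  disc[(rr - 51)^2 + (cc - 51)^2 <= 40^2] <- 1
  for (s in c(0, 0.5, 1, 2, -3, Inf)) {
    for (d in c(1, -1)) {
      e <- cast_normal_ray(disc, c(51, 51), s, d)
      len <- sqrt(sum((e - c(51, 51))^2))
      expect_gte(len, 40 - sqrt(2) - 1e-9)
      expect_lte(len, 40 + 1e-9)
    }
  }
})

test_that("diameter records satisfy the distance contract", {
  sil <- matrix(0, 121, 31); sil[10:110, ] <- 1
  line <- as_centreline(cbind(rep(60L, 21), 6:26))
  rec <- diameter_at(sil, line, 10)
  expect_equal(rec$diameter_px, 100)
  expect_equal(c(rec$end1_row, rec$end2_row), c(110, 10))
  # degenerate 1-px-thick silhouette: coincident endpoints, d = 0
  thin <- matrix(0, 9, 31); thin[5, ] <- 1
  tl <- as_centreline(cbind(rep(5L, 21), 6:26))
  expect_equal(diameter_at(thin, tl, 10)$diameter_px, 0)
})

test_that("width profile trims the valid domain and summarises over it", {
  sil <- matrix(0, 61, 200); sil[20:40, ] <- 1
  line <- as_centreline(cbind(rep(30L, 190), 6:195))
  prof <- width_profile(sil, line, trim = 20)
  expect_s3_class(prof, "tube_profile")
  expect_equal(attr(prof, "valid_domain"), c(21, 170))
  s <- summary(prof)
  expect_equal(s$mean_valid, 20)
  expect_equal(s$sd_valid, 0)
  expect_error(width_profile(sil, line, trim = 200), "valid domain")
  # ray endpoint invariant: next pixel beyond each endpoint is background
  expect_true(all(sil[cbind(prof$end1_row, prof$end1_col)] == 1))
  expect_true(all(prof$end1_row == 40 | prof$end1_row == 20))
})

test_that("calibration converts pixels to millimetres linearly", {
  sil <- matrix(0, 71, 60); sil[20:55, ] <- 1   # 36 rows: d = 35 px
  line <- as_centreline(cbind(rep(37L, 40), 11:50))
  prof <- width_profile(sil, line, trim = 5)
  cal <- calibrate(prof, 35)
  rec35 <- cal$diameter_mm[cal$diameter_px == 35]
  expect_equal(rec35, rep(1, length(rec35)))   # 35 px at 35 px/mm = 1 mm
  expect_equal(calibrate(prof, 1)$diameter_mm, prof$diameter_px)
  expect_equal(calibrate(prof, 70)$diameter_mm,
               calibrate(prof, 35)$diameter_mm / 2)
  expect_error(calibrate(prof, 0), "positive")
})

test_that("profile CSV round-trips the records", {
  sil <- matrix(0, 61, 60); sil[20:40, ] <- 1
  line <- as_centreline(cbind(rep(30L, 40), 11:50))
  prof <- width_profile(sil, line, trim = 5, pixels_per_mm = 35)
  f <- tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  back <- utils::read.csv(f)
  expect_equal(back$diameter_px, prof$diameter_px)
  expect_equal(back$diameter_mm, prof$diameter_mm)
  unlink(f)
})
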