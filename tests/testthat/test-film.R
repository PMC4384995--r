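test_that("mean_gray averages the ROI and validates dimensions", {
  img <- film_image(matrix(37, 50, 50))
  expect_equal(mean_gray(img, roi_size = 20), 37)

  half <- film_image(cbind(matrix(0, 40, 20), matrix(255, 40, 20)))
  expect_equal(mean_gray(half, roi_size = 40), 127.5)

  expect_error(mean_gray(img, roi_size = 100), "larger than image")
  expect_error(film_image(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(film_image(matrix(-3, 2, 2)), "\\[0, 255\\]")
})

test_that("mean_gray equals the mixture of film and background grays given the hole mask", {
  spec <- film_sim_spec(degraded_fraction = 0.35, noise_sd = 0, seed = 42)
  sim <- simulate_film_image(spec)
  b <- locate_roi(sim$image, roi_size = 300, threshold = 120)
  roi_mask <- sim$mask[b[1]:b[2], b[3]:b[4]]
  f_roi <- mean(roi_mask)
  expect_equal(mean_gray(sim$image, 300, threshold = 120),
               (1 - f_roi) * spec$gray_film + f_roi * spec$gray_background)
})

test_that("RGB input collapses to one gray channel", {
  arr <- array(0, dim = c(10, 10, 3))
  arr[, , 1] <- 30; arr[, , 2] <- 60; arr[, , 3] <- 90
  expect_equal(film_image(arr)$pixels, matrix(60, 10, 10))
  lum <- film_image(arr, rgb_weights = c(0.299, 0.587, 0.114))
  expect_equal(lum$pixels[1, 1], 0.299 * 30 + 0.587 * 60 + 0.114 * 90)
})

test_that("image files round-trip through PNG and TIFF", {
  px <- matrix(seq(0, 255, length.out = 100), 10, 10)
  img <- film_image(round(px))
  for (ext in c("png", "tiff")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_film_image(img, path)
    back <- read_film_image(path)
    expect_equal(back$pixels, img$pixels, tolerance = 1 / 255)
  }
})

test_that("degradation_ratio follows the calibration line without clamping", {
  cal <- gray_calibration(10, 210)
  expect_equal(degradation_ratio(10, cal), 0)
  expect_equal(degradation_ratio(210, cal), 100)
  expect_equal(degradation_ratio(110, cal), 50)
  expect_equal(degradation_ratio(10, gray_calibration(20, 220)), -5)
  expect_error(gray_calibration(100, 100), "calibration error")
})

test_that("degradation_ratio is monotone in the residual gray and affine-invariant", {
  cal <- gray_calibration(25, 230)
  g <- seq(0, 255, by = 5)
  expect_true(all(diff(degradation_ratio(g, cal)) > 0))

  set.seed(7)
  for (i in 1:20) {
    fresh <- runif(1, 0, 100); bg <- runif(1, 150, 255); res <- runif(1, 0, 255)
    a <- runif(1, 0.2, 0.9); b <- runif(1, 0, 20)
    r1 <- degradation_ratio(res, gray_calibration(fresh, bg))
    r2 <- degradation_ratio(a * res + b,
                            gray_calibration(a * fresh + b, a * bg + b))
    expect_equal(r2, r1, tolerance = 1e-9)
  }
})

test_that("replicate summaries report mean, SE and the n = 1 convention", {
  expect_equal(summarize_replicates(c(10, 10, 10)),
               list(mean = 10, se = 0, n = 3L))
  s <- summarize_replicates(c(0, 5, 10))
  expect_equal(s$mean, 5)
  expect_equal(s$se, sd(c(0, 5, 10)) / sqrt(3), tolerance = 1e-12)
  expect_equal(s$se, 2.8868, tolerance = 1e-4)
  expect_true(is.na(summarize_replicates(7.4)$se))
  expect_error(summarize_replicates(numeric(0)), "non-empty")
})

test_that("degradation_rate definitions agree on linear data and differ sensibly otherwise", {
  lin <- weekly_df(c(5, 10, 15))
  for (m in c("endpoint", "mean3", "ols0")) {
    expect_equal(degradation_rate(weekly_df(c(0, 0, 0)), m)$rate, 0)
  }
  # on data linear through the origin the two slope-like definitions agree
  # on the true slope; "mean3" averages the ratios themselves, which on
  # y = 5t equals 5 * mean(1:3) = 10 (the week-2 value)
  expect_equal(degradation_rate(lin, "endpoint")$rate, 5)
  expect_equal(degradation_rate(lin, "ols0")$rate, 5)
  expect_equal(degradation_rate(lin, "mean3")$rate, 10)
  oka <- weekly_df(c(0.4, 3.9, 60.3))
  expect_equal(degradation_rate(oka, "endpoint")$rate, 20.1)
  expect_equal(degradation_rate(oka, "mean3")$rate, 21.533, tolerance = 1e-3)
  expect_equal(degradation_rate(oka, "ols0")$rate,
               (1 * 0.4 + 2 * 3.9 + 3 * 60.3) / 14)
  expect_error(degradation_rate(weekly_df(c(1, 2), weeks = 1:2)),
               "weeks 1-3")
})

test_that("quantify_films assembles a weekly series from replicate scans", {
  cal <- gray_calibration(20, 220)
  mk <- function(g) film_image(matrix(g, 40, 40))
  images <- list(
    `1` = list(mk(20), mk(30), mk(40)),   # ratios 0, 5, 10
    `2` = list(mk(60), mk(70), mk(80)),   # 20, 25, 30
    `3` = list(mk(120), mk(140), mk(160)) # 50, 60, 70
  )
  ds <- quantify_films(images, cal, soil_id = "T", roi_size = 20)
  expect_equal(ds$weekly$mean, c(5, 25, 60))
  expect_equal(ds$weekly$n, c(3L, 3L, 3L))
  expect_equal(ds$rate_percent_per_week, 20)
  expect_equal(nrow(ds$per_replicate), 9L)
})
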