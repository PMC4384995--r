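test_that("film generator hits the target fraction exactly and reproducibly", {
  for (f in c(0, 0.3, 0.7, 1)) {
    spec <- film_sim_spec(degraded_fraction = f, seed = 123)
    sim <- simulate_film_image(spec)
    npix <- spec$width * spec$height
    expect_equal(sum(sim$mask), round(f * npix))
    # exact fraction also inside the central control window
    win <- spec$control_window
    r0 <- floor((spec$height - win) / 2) + 1L
    c0 <- floor((spec$width - win) / 2) + 1L
    roi <- sim$mask[r0:(r0 + win - 1L), c0:(c0 + win - 1L)]
    expect_equal(sum(roi), round(f * win^2))
  }
  a <- simulate_film_image(film_sim_spec(degraded_fraction = 0.4, seed = 9))
  b <- simulate_film_image(film_sim_spec(degraded_fraction = 0.4, seed = 9))
  expect_identical(a$image$pixels, b$image$pixels)
})

test_that("film pipeline recovers the degraded fraction at the edge cases", {
  for (f in c(0, 1)) {
    spec <- film_sim_spec(degraded_fraction = f, seed = 77)
    sim <- simulate_film_image(spec)
    cal <- simulate_calibration_images(spec)$calibration
    thr <- (spec$gray_film + spec$gray_background) / 2
    ratio <- degradation_ratio(mean_gray(sim$image, 300, threshold = thr), cal)
    expect_lt(abs(ratio - 100 * f), 0.5)
  }
})

test_that("simulated plate counts have Poisson and binomial moments", {
  obs <- simulate_plates(0, dilutions = c(10, 100), seed = 1)
  expect_true(all(obs$colonies_total == 0))

  # expected count 50: density such that D * 0.8 / 10 * 0.1 / 100 = 50
  D <- 50 * 100 * 10 / 0.1 / 0.8
  obs <- simulate_plates(D, degrader_fraction = 0.423, dilutions = 100,
                         n_plates = 1000, seed = 42)
  m <- mean(obs$colonies_total)
  expect_lt(abs(m - 50), 3 * sqrt(50 / 1000))
  frac <- sum(obs$colonies_clearing) / sum(obs$colonies_total)
  se <- sqrt(0.423 * 0.577 / sum(obs$colonies_total))
  expect_lt(abs(frac - 0.423), 3 * se)
})

test_that("timecourse with zero growth leaves treatments exchangeable, with growth it trends", {
  flat <- simulate_timecourse(soil_sim_spec(growth_rate = 0, seed = 3))
  expect_equal(flat$truth$density_with_film, flat$truth$density_without_film)
  # the static baseline population still degrades film at a constant speed
  expect_equal(flat$degradation$true_ratio[1], 0)
  expect_equal(diff(flat$degradation$true_ratio),
               rep(diff(flat$degradation$true_ratio)[1], 4))

  tc <- simulate_timecourse(soil_sim_spec(seed = 3))
  expect_true(all(diff(tc$truth$density_with_film) > 0))
  expect_true(all(diff(tc$degradation$true_ratio) > 0))
  # near-linear over weeks 0-3: growth-phase increments comparable
  inc <- diff(tc$degradation$true_ratio[1:4])
  expect_lt(max(inc) / min(inc), 5)

  # noise-free absorbances invert to the true activities exactly
  nf <- simulate_timecourse(soil_sim_spec(absorbance_noise_sdlog = 0,
                                          seed = 4))
  act <- esterase_activities(nf$absorbances)$summary
  wf <- act[act$treatment == "with_film", ]
  expect_equal(wf$gmean_activity[order(wf$timepoint_week)],
               nf$truth$activity_with_film, tolerance = 1e-9)
})

test_that("multisoil generator controls the rank correlation through the copula", {
  perfect <- simulate_multisoil(soil_sim_spec(target_rho = 1, seed = 2))
  expect_equal(spearman(perfect$isolation_rate_percent,
                        perfect$degradation_rate_percent_per_week)$rho, 1)
  # the latent uniforms and the emitted marginals share ranks exactly
  ms <- simulate_multisoil(soil_sim_spec(target_rho = 0.63, seed = 8))
  expect_equal(rank(ms$isolation_rate_percent), rank(ms$u_isolation))
  expect_equal(rank(ms$degradation_rate_percent_per_week), rank(ms$u_rate))
  expect_warning(simulate_multisoil(soil_sim_spec(n_soils = 4, seed = 1)),
                 "n < 5")
})
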