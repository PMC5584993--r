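test_that("Gaussian receptive fields have the FWHM geometry", {
  rf <- gaussian_rf(5.73)
  expect_equal(rf$sigma, 5.73 / sqrt(8 * log(2)))
  expect_lt(abs(rf$sigma - 2.433), 0.001)
  prof <- rhabdom:::rf_profile(rf, seq(-30, 30, by = 0.01))
  expect_lt(abs(sum(prof) * 0.01 - 1), 1e-6)
  expect_equal(rhabdom:::rf_profile(rf, 5.73 / 2) / rhabdom:::rf_profile(rf, 0),
               0.5, tolerance = 1e-12)
  expect_error(gaussian_rf(0), "positive")
})

test_that("static light input matches a brute-force spatial integral", {
  rf <- gaussian_rf(8.1)
  scene <- moving_dot_scene(0, 40, dot_intensity = 2, background = 0.1)
  li <- static_light_input(rf, scene)
  # brute-force oracle: dense azimuth grid, numerical convolution
  az <- seq(-40, 40, by = 0.002)
  prof <- rhabdom:::rf_profile(rf, az)
  oracle <- function(t) {
    p <- rhabdom:::dot_positions(scene, t)
    in_dot <- (abs(az - p[1]) <= scene$dot_size / 2) +
      (abs(az - p[2]) <= scene$dot_size / 2)
    scene$background + sum(2 * in_dot * prof) * 0.002
  }
  for (t in c(0.2, 0.35, 0.375, 0.41)) {
    expect_lt(abs(li$values[round(t * 1000) + 1] - oracle(t)), 1e-3)
  }
  # temporal FWHM of a single dot's passage = spatial blur width / speed
  single <- moving_dot_scene(0, 40, dot_intensity = 1)
  v <- static_light_input(rf, single)$values - single$background
  t_fwhm <- sum(v >= max(v) / 2) * 0.001
  spatial <- scene_fwhm <- {
    prof_blur <- vapply(az, function(a)
      sum(prof[abs(az - a) <= single$dot_size / 2]) * 0.002, numeric(1))
    sum(prof_blur >= max(prof_blur) / 2) * 0.002
  }
  expect_lt(abs(t_fwhm - spatial / 40) / (spatial / 40), 0.05)

  # intensity linearity: doubling the dot intensity doubles the dot-driven
  # part of the light input
  pair <- static_light_input(rf, moving_dot_scene(6.8, 100, background = 0.1))
  pair2 <- static_light_input(rf, moving_dot_scene(6.8, 100, background = 0.1,
                                                   dot_intensity = 2))
  expect_equal(pair2$values - 0.1, 2 * (pair$values - 0.1))

  # a uniform (dot-free) scene yields a constant series
  bgonly <- moving_dot_scene(6.8, 100, dot_intensity = 0, background = 0.4)
  expect_equal(var(static_light_input(rf, bgonly)$values), 0)
})

test_that("Volterra predictions blur as the classic theory says", {
  scene <- moving_dot_scene(6.8, 50)
  delta <- structure(list(kernel = 1, dt = 0.001), class = "impulse_response")
  expect_equal(volterra_predict(gaussian_rf(6), delta, scene),
               static_light_input(gaussian_rf(6), scene)$values)

  # broader acceptance angles strictly lower the dip
  k <- impulse_response(duration_s = 0.05)
  Ds <- vapply(c(4, 5, 6), function(dr)
    rayleigh_resolvability(volterra_predict(gaussian_rf(dr), k, scene),
                           smooth_ms = 0)$D, numeric(1))
  expect_true(all(diff(Ds) < 0))

  # the classic model fails on double-fast dots through a realistic field
  fast <- moving_dot_scene(6.8, 409)
  Dfast <- rayleigh_resolvability(volterra_predict(gaussian_rf(8), k, fast),
                                  smooth_ms = 0)$D
  expect_lt(Dfast, 1)
})

test_that("Rayleigh resolvability matches the two-Gaussian closed form", {
  tt <- seq(-6, 6, by = 0.001)
  for (sigma in c(0.5, 0.8)) for (sep in sigma * c(3, 3.5, 4)) {
    y <- dnorm(tt, -sep / 2, sigma) + dnorm(tt, sep / 2, sigma)
    y <- y / max(y)
    D <- rayleigh_resolvability(y, smooth_ms = 0)$D
    expect_lt(abs(D - rhabdom:::two_gaussian_dip(sep, sigma)), 1)
  }

  # single pulse and monotone traces are unresolved, not errors
  expect_equal(rayleigh_resolvability(dnorm(tt), smooth_ms = 0)$D, 0)
  expect_false(rayleigh_resolvability(seq_len(100) / 100)$resolved)

  # a static 5.73-degree field viewing point dots 6.8 degrees apart
  # reproduces the closed-form dip
  li <- static_light_input(gaussian_rf(5.73),
                           moving_dot_scene(6.8, 20, dot_size = 0.01))
  D <- rayleigh_resolvability(li$values, smooth_ms = 0)$D
  expect_lt(abs(D - rhabdom:::two_gaussian_dip(6.8, 2.433)), 1.5)
})

test_that("microsaccade kinetics reproduce the measured flash dynamics", {
  kin <- microsaccade_kinetics()
  dark <- microsaccade_displacement(numeric(500), kin)
  expect_equal(max(dark$displacement_um), 0)
  expect_equal(dark$delta_rho_deg, rep(kin$delta_rho_rest, 500))

  # saturating step: movement starts 8-20 ms after onset, maximal
  # displacement 70-200 ms after onset, amplitude at the 1.2 um ceiling
  step <- c(numeric(20), rep(kin$i_sat, 1480))
  d <- microsaccade_displacement(step, kin)$displacement_um
  onset <- which(d > 0.01 * max(d))[1] - 21
  peak <- which.max(d) - 21
  expect_gte(onset, 8)
  expect_lte(onset, 20)
  expect_gte(peak, 70)
  expect_lte(peak, 200)
  expect_equal(max(d), kin$max_displacement_um, tolerance = 1e-6)

  # logarithmic sensitivity: ten-fold intensity steps give near-equal
  # displacement increments (brief flashes, below the output ceiling)
  peaks <- vapply(c(0.1, 1, 10), function(I) {
    fl <- c(numeric(50), rep(I, 3), numeric(800))
    max(microsaccade_displacement(fl, kin)$displacement_um)
  }, numeric(1))
  incr <- diff(peaks)
  expect_gt(incr[2] / incr[1], 0.7)
  expect_lt(incr[2] / incr[1], 1.4)

  # the receptive field moves front-to-back and narrows towards 4 degrees
  li <- microsaccadic_light_input(moving_dot_scene(6.8, 205),
                                  gaussian_rf(8.1), kin)
  expect_gte(min(attr(li, "delta_rho_deg")), kin$delta_rho_contracted - 1e-9)
  expect_gte(max(attr(li, "center_deg")), 3)
})

test_that("zero-amplitude kinetics reduce to the static pipeline", {
  rf <- gaussian_rf(8.1)
  kin0 <- microsaccade_kinetics(max_displacement_um = 0)
  scene <- moving_dot_scene(6.8, 205)
  expect_equal(microsaccadic_light_input(scene, rf, kin0)$values,
               static_light_input(rf, scene)$values, tolerance = 1e-12)

  p <- sampling_params(n_microvilli = 5000)
  a0 <- simulate_acuity(scene, rf, kin0, p, n_trials = 3, seed = 99)
  a1 <- simulate_acuity(scene, rf, NULL, p, n_trials = 3, seed = 99)
  expect_identical(a0$ensemble$y, a1$ensemble$y)
})

test_that("moving dots become two intensity spikes under microsaccades", {
  rf <- gaussian_rf(8.1)
  kin <- microsaccade_kinetics()
  for (speed in c(205, 409)) {
    li <- microsaccadic_light_input(moving_dot_scene(6.8, speed), rf, kin)
    r <- rayleigh_resolvability(li$values, smooth_ms = 0)
    expect_true(r$resolved)
    st <- rayleigh_resolvability(
      static_light_input(rf, moving_dot_scene(6.8, speed))$values,
      smooth_ms = 0)
    expect_gt(r$D, st$D)
  }
})

test_that("back-to-front crossings lead front-to-back at the half-maximum", {
  rf <- gaussian_rf(8.1)
  kin <- microsaccade_kinetics()
  p <- sampling_params()
  leads <- vapply(c(205, 409), function(speed) {
    f2b <- simulate_acuity(moving_dot_scene(6.8, speed, direction = "front_to_back"),
                           rf, kin, p, n_trials = 10, seed = 77)
    b2f <- simulate_acuity(moving_dot_scene(6.8, speed, direction = "back_to_front"),
                           rf, kin, p, n_trials = 10, seed = 77)
    1000 * (half_max_times(colMeans(f2b$ensemble$y))[["fall"]] -
              half_max_times(colMeans(b2f$ensemble$y))[["fall"]])
  }, numeric(1))
  expect_true(all(leads > 0))
  expect_gte(mean(leads), 2)
  expect_lte(mean(leads), 10)
})

test_that("microsaccadic resolvability dominates the static model at saccadic speeds", {
  rf <- gaussian_rf(8.1)
  kin <- microsaccade_kinetics()
  p <- sampling_params()
  for (speed in c(100, 205, 300)) {
    mic <- simulate_acuity(moving_dot_scene(6.8, speed), rf, kin, p,
                           n_trials = 5, seed = 13)
    sta <- simulate_acuity(moving_dot_scene(6.8, speed), rf, NULL, p,
                           n_trials = 5, seed = 13)
    expect_gte(mic$resolvability$D, sta$resolvability$D)
  }
})
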