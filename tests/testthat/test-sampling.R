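test_that("photon allocation is uniform over microvilli", {
  a1 <- allocate_photons(0.5, n_microvilli = 100, seed = 1)
  expect_length(a1$times, 1)
  expect_true(a1$microvillus %in% 1:100)

  # chi-square goodness of fit on per-microvillus counts
  pvals <- vapply(1:5, function(s) {
    a <- allocate_photons(runif(5000), n_microvilli = 50, seed = s)
    suppressWarnings(stats::chisq.test(tabulate(a$microvillus, 50))$p.value)
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 1)
})

test_that("refractory transduction follows the sampling rules", {
  p <- sampling_params()
  one <- generate_bumps(allocate_photons(0.1, 30000, seed = 1), p, seed = 2)
  expect_equal(one$n_bumps, 1L)

  # two photons on the same microvillus: 400 ms apart clears the maximal
  # 300 ms refractory period, 10 ms apart never does
  two_far <- structure(list(times = c(0.1, 0.5), microvillus = c(1L, 1L),
                            n_microvilli = 1L), class = "allocation")
  expect_equal(generate_bumps(two_far, p, seed = 3)$n_bumps, 2L)
  two_near <- structure(list(times = c(0.1, 0.11), microvillus = c(1L, 1L),
                             n_microvilli = 1L), class = "allocation")
  expect_equal(generate_bumps(two_near, p, seed = 3)$n_bumps, 1L)

  # bump count never exceeds photon count
  alloc <- allocate_photons(runif(20000, 0, 0.5), 2000, seed = 4)
  bt <- generate_bumps(alloc, p, seed = 5)
  expect_lte(bt$n_bumps, bt$n_photons)
})

test_that("steady-state bump rate matches the dead-time renewal oracle", {
  p <- sampling_params()
  # a microvillus is busy for latency + refractory period
  E <- mean_refractory(p) + p$latency_mean_s
  for (lam in c(2, 5, 10)) {           # per-microvillus photon rates (1/s)
    dur <- 400
    set.seed(round(100 * lam))
    n <- rpois(1, lam * dur)
    alloc <- structure(list(times = sort(runif(n, 0, dur)),
                            microvillus = rep(1L, n), n_microvilli = 1L),
                       class = "allocation")
    bt <- generate_bumps(alloc, p, seed = round(100 * lam) + 1)
    expected <- lam / (1 + lam * E) * dur
    expect_lt(abs(bt$n_bumps - expected), 3 * sqrt(expected))
  }
})

test_that("transduced fraction saturates with brightening light", {
  p <- sampling_params()
  frac <- vapply(c(1e5, 1e6, 1e7), function(rate) {
    set.seed(7)
    tr <- rhabdom:::simulate_trial(rep(rate, 500), 0.001, p)
    tr$n_bumps / tr$n_photons
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
  # doubling an already-bright rate gains less than 2x bumps
  set.seed(9)
  b1 <- rhabdom:::simulate_trial(rep(8e5, 1000), 0.001, p)$n_bumps
  set.seed(10)
  b2 <- rhabdom:::simulate_trial(rep(1.6e6, 1000), 0.001, p)$n_bumps
  expect_gt(b2, b1)
  expect_lt(b2 / b1, 2)
})

test_that("bump summation is linear and obeys Campbell's theorem", {
  p <- sampling_params()
  one <- structure(list(onsets = 0.05, amplitudes = p$bump_amplitude,
                        n_photons = 1L, n_bumps = 1L), class = "bump_train")
  y1 <- sum_bumps(one, p, n_bins = 200)
  h <- rhabdom:::bump_waveform(p, 0.001)
  expect_equal(sum(y1), p$bump_amplitude * sum(h), tolerance = 1e-10)

  # superposition of disjoint trains
  t2 <- structure(list(onsets = 0.12, amplitudes = p$bump_amplitude,
                       n_photons = 1L, n_bumps = 1L), class = "bump_train")
  both <- structure(list(onsets = c(0.05, 0.12),
                         amplitudes = rep(p$bump_amplitude, 2),
                         n_photons = 2L, n_bumps = 2L), class = "bump_train")
  expect_equal(sum_bumps(both, p, n_bins = 200),
               y1 + sum_bumps(t2, p, n_bins = 200))

  # Campbell's theorem: variance of the shot-noise output of a stationary
  # Poisson bump train equals rate * dt * amplitude^2 * sum(h^2)
  set.seed(21)
  r <- 200
  counts <- rpois(2e5, r * 0.001)
  y <- sum_bumps(counts, p)
  pred_var <- r * 0.001 * p$bump_amplitude^2 * sum(h^2)
  expect_lt(abs(var(y[500:2e5]) / pred_var - 1), 0.05)

  # and the noise PSD follows the bump waveform's power spectrum
  seg <- matrix(y[1:(97 * 1024)], nrow = 1024)
  psd <- rowMeans(apply(seg, 2, function(x) Mod(fft(x - mean(x)))^2))[2:400]
  href <- (Mod(fft(c(h, numeric(1024 - length(h)))))^2)[2:400]
  expect_gt(cor(psd, href), 0.95)
})

test_that("membrane stage is linear, causal and information-invariant", {
  y <- membrane_transform(rep(2, 3000), tau_m = 0.01, gain = 3)
  expect_lt(abs(tail(y, 1) - 6), 1e-6)
  step <- membrane_transform(c(numeric(10), rep(1, 200)), 0.02)
  expect_lt(abs(step[10 + 20] - (1 - exp(-1))), 0.03)
  expect_equal(membrane_transform(1:5, 0, gain = 2), c(2, 4, 6, 8, 10))
  expect_error(membrane_transform(1:5, -1), "non-negative")

  # one common linear filter on every trial leaves SNR(f) and the Shannon
  # rate essentially unchanged
  ens <- sine_ensemble(n_trials = 12, seed = 31)
  r0 <- shannon_rate(snr_spectrum(ens))$R
  yf <- t(apply(ens$y, 1, membrane_transform, tau_m = 0.01, gain = 2))
  r1 <- shannon_rate(snr_spectrum(response_ensemble(yf, ens$dt)))$R
  expect_lt(abs(r1 - r0) / r0, 0.02)
})

test_that("the fused engine matches the explicit sampling chain", {
  p <- sampling_params()
  rate <- rep(2e5, 2000)
  set.seed(41)
  eng <- rhabdom:::simulate_trial(rate, 0.001, p)
  set.seed(42)
  n <- rpois(1, 2e5 * 2)
  alloc <- allocate_photons(runif(n, 0, 2), p$n_microvilli, seed = 43)
  bt <- generate_bumps(alloc, p, seed = 44)
  # independent stochastic routes through the same model: bump counts agree
  # to within a few Poisson standard errors
  expect_lt(abs(eng$n_bumps - bt$n_bumps) / bt$n_bumps, 0.02)
})

test_that("ensembles are reproducible and respect degenerate input", {
  p <- sampling_params(n_microvilli = 2000)
  dark <- light_series(rep(0, 300), 0.001)
  ed <- simulate_ensemble(dark, 1e5, p, 2, seed = 1)
  expect_true(all(ed$y == 0))   # zero light -> flat zero ensemble
  stim <- burst_stimulus(100, 0.5, duration_s = 0.5, seed = 3)
  e1 <- simulate_ensemble(stim, 5e4, p, 3, seed = 7)
  e2 <- simulate_ensemble(stim, 5e4, p, 3, seed = 7)
  expect_identical(e1$y, e2$y)
  expect_error(simulate_ensemble(stim, -1, p, 3), "positive")
})

test_that("photon-rate optimization returns the argmax and trivial grids", {
  stim <- burst_stimulus(100, 0, duration_s = 1, seed = 5)
  p <- sampling_params()
  single <- optimize_photon_rate(stim, 2e5, p, n_trials = 3, seed = 8)
  expect_equal(single$best_rate, 2e5)
  opt <- optimize_photon_rate(stim, c(1e4, 4e5), p, n_trials = 4, seed = 8)
  expect_equal(opt$best_rate, 4e5)  # brighter of the two wins well below saturation
  expect_equal(nrow(opt$profile), 2)
  expect_error(optimize_photon_rate(stim, numeric(0)), "non-empty")
})

test_that("fitting the dead-time law recovers the mean refractory period", {
  p <- sampling_params()
  rf <- p$refractory
  rates <- c(2e4, 1e5, 4e5, 1e6, 4e6)
  # steady-state per-microvillus bump rates, pool warm-up discarded
  r_m <- vapply(seq_along(rates), function(i) {
    set.seed(60 + i)
    eng <- rhabdom:::sample_bumps_cpp(rep(rates[i], 1500), 0.001,
                                      p$n_microvilli, p$lat_shape,
                                      p$lat_scale, rf$meanlog, rf$sdlog,
                                      rf$min, rf$max)
    sum(eng$bumps[501:1500]) / p$n_microvilli
  }, numeric(1))
  lam <- rates / p$n_microvilli
  # 1/r = 1/lambda + E_busy, a straight line in 1/lambda
  fit <- lm(I(1 / r_m) ~ I(1 / lam))
  E_ref <- coef(fit)[[1]] - p$latency_mean_s
  expect_lt(abs(E_ref - mean_refractory(p)) / mean_refractory(p), 0.1)
})
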