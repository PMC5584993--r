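#' Parameters of the refractory photon-sampling model
#'
#' A photoreceptor's rhabdomere is modelled as `n_microvilli` independent
#' sampling units. A photon landing on a free microvillus elicits one
#' quantum bump after a stochastic latency; the microvillus is then
#' refractory (50-300 ms) and photons arriving during the latency or the
#' refractory period are lost. Bumps have a fixed amplitude and a gamma
#' waveform, and the summed bump current passes a first-order membrane
#' low-pass.
#'
#' Default distributions (latency and refractory period laws are not fixed
#' by the range constraints alone, and are calibrated once; see the methods
#' vignette): refractory period log-normal truncated to \[50, 300\] ms,
#' latency gamma-distributed with mean `latency_mean_s` and CV
#' `latency_cv`.
#'
#' @param n_microvilli number of sampling units (default 30000).
#' @param refractory list: `meanlog`, `sdlog`, `min`, `max` (seconds) of the
#'   truncated log-normal refractory distribution.
#' @param latency_mean_s mean bump latency (s).
#' @param latency_cv coefficient of variation of the latency.
#' @param bump_order gamma waveform shape order n (waveform
#'   `h(t) ~ (t/tau)^(n-1) exp(-t/tau)`).
#' @param bump_t_peak_s bump time-to-peak (s).
#' @param bump_amplitude bump amplitude (response units).
#' @param tau_m_s membrane time constant (s); 0 disables the low-pass.
#' @param gain static membrane gain.
#' @return A `sampling_params` object.
#' @export
sampling_params <- function(n_microvilli = 30000,
                            refractory = list(meanlog = -1.3436,
                                              sdlog = 0.35,
                                              min = 0.05, max = 0.30),
                            latency_mean_s = 0.012,
                            latency_cv = 0.6,
                            bump_order = 3,
                            bump_t_peak_s = 0.004,
                            bump_amplitude = 1,
                            tau_m_s = 0.002,
                            gain = 1) {
  stopifnot(n_microvilli >= 1,
            refractory$min >= 0.05 - 1e-12, refractory$max <= 0.30 + 1e-12,
            latency_mean_s > 0, latency_cv > 0,
            bump_order >= 1, bump_t_peak_s > 0, tau_m_s >= 0)
  lat_shape <- 1 / latency_cv^2
  structure(list(n_microvilli = as.integer(n_microvilli),
                 refractory = refractory,
                 latency_mean_s = latency_mean_s, latency_cv = latency_cv,
                 lat_shape = lat_shape, lat_scale = latency_mean_s / lat_shape,
                 bump_order = bump_order, bump_t_peak_s = bump_t_peak_s,
                 bump_amplitude = bump_amplitude,
                 tau_m_s = tau_m_s, gain = gain),
            class = "sampling_params")
}

#' @export
print.sampling_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sampling_params> %d microvilli | refractory mean %.0f ms ",
           "[%.0f, %.0f] | latency %.1f ms (CV %.2f) | bump t_peak %.1f ms\n"),
    x$n_microvilli, 1000 * mean_refractory(x), 1000 * x$refractory$min,
    1000 * x$refractory$max, 1000 * x$latency_mean_s, x$latency_cv,
    1000 * x$bump_t_peak_s))
  invisible(x)
}

#' Mean refractory period of a parameter set
#'
#' @param params a `sampling_params` object.
#' @return Mean of the truncated log-normal refractory period, in seconds.
#' @export
mean_refractory <- function(params) {
  r <- params$refractory
  truncated_lognormal_mean(r$meanlog, r$sdlog, r$min, r$max)
}

# draw truncated log-normal refractory periods by inverse-CDF sampling
draw_refractory <- function(n, refractory) {
  plo <- plnorm(refractory$min, refractory$meanlog, refractory$sdlog)
  phi <- plnorm(refractory$max, refractory$meanlog, refractory$sdlog)
  qlnorm(plo + runif(n) * (phi - plo), refractory$meanlog, refractory$sdlog)
}

#' Allocate photons uniformly over microvilli
#'
#' Each photon is assigned independently and uniformly to one microvillus
#' (the rhabdomere waveguide spreads light over the whole microvillar
#' stack). Accepts either a vector of photon event times or a
#' `photon_stream`, in which case the requested trial's per-bin counts are
#' jittered uniformly within their bins.
#'
#' @param photons numeric vector of photon times (s), or a `photon_stream`.
#' @param n_microvilli number of sampling units.
#' @param seed optional integer seed.
#' @param trial trial index used when `photons` is a `photon_stream`.
#' @return An `allocation` object: list with sorted `times`, `microvillus`
#'   ids, `n_microvilli`.
#' @export
allocate_photons <- function(photons, n_microvilli = 30000, seed = NULL,
                             trial = 1) {
  if (n_microvilli < 1) stop("n_microvilli must be at least 1")
  maybe_set_seed(seed)
  if (inherits(photons, "photon_stream")) {
    cnt <- photons$counts[trial, ]
    times <- rep((seq_along(cnt) - 1) * photons$dt, cnt) +
      runif(sum(cnt)) * photons$dt
  } else {
    times <- as.numeric(photons)
  }
  o <- order(times)
  times <- times[o]
  mv <- sample.int(n_microvilli, length(times), replace = TRUE)
  structure(list(times = times, microvillus = mv,
                 n_microvilli = as.integer(n_microvilli)),
            class = "allocation")
}

#' Transduce allocated photons into quantum bumps
#'
#' Applies the refractory sampling rule: a photon on a free microvillus
#' yields one bump after a gamma-distributed latency, after which the unit
#' is refractory for a truncated log-normal period; photons arriving during
#' the latency or refractory period are lost. Losses are the model, not
#' errors.
#'
#' @param alloc an `allocation` from [allocate_photons()].
#' @param params a `sampling_params` object.
#' @param seed optional integer seed.
#' @return A `bump_train`: list with bump `onsets` (s, sorted),
#'   `amplitudes`, `n_photons`, `n_bumps`.
#' @export
generate_bumps <- function(alloc, params = sampling_params(), seed = NULL) {
  stopifnot(inherits(alloc, "allocation"))
  maybe_set_seed(seed)
  n <- length(alloc$times)
  if (n == 0) {
    return(structure(list(onsets = numeric(0), amplitudes = numeric(0),
                          n_photons = 0L, n_bumps = 0L),
                     class = "bump_train"))
  }
  lat <- rgamma(n, shape = params$lat_shape, scale = params$lat_scale)
  refr <- draw_refractory(n, params$refractory)
  acc <- refractory_filter_cpp(alloc$times, alloc$microvillus, lat, refr,
                               alloc$n_microvilli)
  onsets <- sort(alloc$times[acc] + lat[acc])
  structure(list(onsets = onsets,
                 amplitudes = rep(params$bump_amplitude, length(onsets)),
                 n_photons = n, n_bumps = length(onsets)),
            class = "bump_train")
}

# normalized gamma bump waveform sampled on the bin grid (peak = 1)
bump_waveform <- function(params, dt) {
  tau <- params$bump_t_peak_s / (params$bump_order - 1)
  tt <- seq(0, params$bump_t_peak_s + 12 * tau, by = dt)
  h <- (tt / tau)^(params$bump_order - 1) * exp(-tt / tau)
  h / max(h)
}

#' Sum quantum bumps into a macroscopic current-like trace
#'
#' `response(t) = sum_k amplitude_k * h(t - t_k)` with `h` the normalized
#' gamma bump waveform. Accepts a `bump_train` or a vector of per-bin bump
#' counts.
#'
#' @param bumps a `bump_train`, or numeric per-bin bump counts.
#' @param params a `sampling_params` object.
#' @param n_bins output length in bins.
#' @param dt bin width (s).
#' @return Numeric response vector of length `n_bins`.
#' @export
sum_bumps <- function(bumps, params = sampling_params(), n_bins, dt = 0.001) {
  if (inherits(bumps, "bump_train")) {
    idx <- floor(bumps$onsets / dt) + 1
    keep <- idx >= 1 & idx <= n_bins
    counts <- numeric(n_bins)
    if (any(keep)) {
      tab <- tabulate(idx[keep], nbins = n_bins)
      counts <- tab * params$bump_amplitude
    }
  } else {
    counts <- as.numeric(bumps) * params$bump_amplitude
    n_bins <- length(counts)
  }
  h <- bump_waveform(params, dt)
  nh <- length(h)
  out <- stats::filter(c(numeric(nh), counts), h, method = "convolution",
                       sides = 1)
  as.numeric(out[nh + seq_len(n_bins)])
}

#' First-order membrane low-pass
#'
#' Linear RC stage with time constant `tau_m` and static gain. With
#' `tau_m = 0` the input is returned scaled by the gain. Because the same
#' filter acts on every trial, signal-to-noise spectra and Shannon rates
#' are invariant to this stage.
#'
#' @param x numeric input series.
#' @param tau_m membrane time constant (s, >= 0).
#' @param gain static gain.
#' @param dt sampling interval (s).
#' @return Filtered numeric vector.
#' @export
membrane_transform <- function(x, tau_m, gain = 1, dt = 0.001) {
  if (tau_m < 0) stop("tau_m must be non-negative")
  if (tau_m == 0) return(gain * x)
  a <- exp(-dt / tau_m)
  y <- stats::filter(gain * (1 - a) * x, a, method = "recursive")
  as.numeric(y)
}

# fast fused per-trial chain (C++ engine): absolute per-bin photon rates ->
# membrane-filtered response. Distribution-identical to the explicit
# allocate_photons -> generate_bumps -> sum_bumps -> membrane_transform chain.
simulate_trial <- function(rate, dt, params) {
  r <- params$refractory
  eng <- sample_bumps_cpp(rate, dt, params$n_microvilli,
                          params$lat_shape, params$lat_scale,
                          r$meanlog, r$sdlog, r$min, r$max)
  y <- sum_bumps(eng$bumps, params, dt = dt)
  y <- membrane_transform(y, params$tau_m_s, params$gain, dt)
  list(y = y, n_photons = eng$n_photons, n_bumps = eng$n_bumps)
}

#' Simulate a repeated-trial response ensemble
#'
#' Runs the full chain photon stream -> allocation -> refractory bump
#' generation -> bump summation -> membrane filter for `n_trials`
#' independent trials of the same light stimulus.
#'
#' @param series a `light_series` (or `photon_stream`, whose rate profile is
#'   reused).
#' @param mean_rate time-averaged absorbed photon rate (photons/s).
#' @param params a `sampling_params` object.
#' @param n_trials number of independent trials (>= 2).
#' @param seed optional master seed; per-trial child seeds are derived.
#' @return A `response_ensemble`: list with `y` (trials x bins matrix),
#'   `dt`, `n_photons`, `n_bumps` (per trial), `provenance`.
#' @export
simulate_ensemble <- function(series, mean_rate, params = sampling_params(),
                              n_trials = 20, seed = NULL) {
  stopifnot(n_trials >= 2)
  if (mean_rate <= 0) stop("mean_rate must be positive")
  m <- mean(series$values)
  rate <- if (m > 0) series$values / m * mean_rate else series$values * 0
  simulate_ensemble_rates(rate, series$dt, params, n_trials, seed,
                          provenance = list(mean_rate = mean_rate,
                                            background = series$background,
                                            cutoff_hz = series$cutoff_hz,
                                            seed = seed))
}

# shared driver over absolute per-bin rates (photons/s)
simulate_ensemble_rates <- function(rate, dt, params, n_trials, seed,
                                    provenance = list()) {
  seeds <- child_seeds(seed, n_trials)
  nb <- length(rate)
  y <- matrix(0, nrow = n_trials, ncol = nb)
  n_photons <- n_bumps <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    maybe_set_seed(seeds[[i]])
    tr <- simulate_trial(rate, dt, params)
    y[i, ] <- tr$y
    n_photons[i] <- tr$n_photons
    n_bumps[i] <- tr$n_bumps
  }
  structure(list(y = y, dt = dt, n_photons = n_photons, n_bumps = n_bumps,
                 provenance = provenance),
            class = "response_ensemble")
}

#' Construct a response ensemble from a trials x time matrix
#'
#' @param y trials x time numeric matrix.
#' @param dt sampling interval (s).
#' @param provenance optional metadata list.
#' @return A `response_ensemble`.
#' @export
response_ensemble <- function(y, dt = 0.001, provenance = list()) {
  y <- as.matrix(y)
  stopifnot(dt > 0, nrow(y) >= 1)
  structure(list(y = y, dt = dt, provenance = provenance),
            class = "response_ensemble")
}

#' @export
print.response_ensemble <- function(x, ...) {
  cat(sprintf("<response_ensemble> %d trials x %d bins (dt %.4g ms)\n",
              nrow(x$y), ncol(x$y), x$dt * 1000))
  invisible(x)
}

#' Optimize the mean absorbed photon rate for information transfer
#'
#' Simulates the photoreceptor at every rate in `rate_grid`, scores each by
#' the Shannon information rate of the output ensemble, and returns the
#' argmax rate with the full information profile. This mimics the action of
#' the photomechanical adaptations (pupil and rhabdomere contractions),
#' which regulate the absorbed photon rate so that response information is
#' maximal.
#'
#' @param series a `light_series`.
#' @param rate_grid photon rates to test (photons/s).
#' @param params a `sampling_params` object.
#' @param n_trials trials per grid point.
#' @param seed optional master seed (re-used per grid point so rates are
#'   compared on matched noise realizations).
#' @return List with `best_rate`, `best_rate_bits` and `profile`
#'   (data.frame: rate, bits_per_s).
#' @export
optimize_photon_rate <- function(series, rate_grid, params = sampling_params(),
                                 n_trials = 10, seed = NULL) {
  if (length(rate_grid) == 0) stop("rate_grid must be non-empty")
  bits <- vapply(rate_grid, function(r) {
    ens <- simulate_ensemble(series, r, params, n_trials, seed)
    shannon_rate(snr_spectrum(ens))$R
  }, numeric(1))
  i <- which.max(bits)
  list(best_rate = rate_grid[i], best_rate_bits = bits[i],
       profile = data.frame(rate = rate_grid, bits_per_s = bits))
}
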