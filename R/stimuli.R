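#' Band-limited Gaussian white-noise contrast series
#'
#' Draws a Gaussian white-noise modulation sequence, low-pass filters it with
#' a Fourier-domain brick wall at `cutoff_hz`, and rescales it so that the
#' post-filter standard deviation equals `peak_to_peak / 6` (the 6-sigma
#' peak-to-peak convention: roughly 99.7% of draws fall inside the nominal
#' modulation range). The result has (sampling) zero mean and a flat power
#' spectrum up to the cutoff.
#'
#' @param cutoff_hz low-pass cutoff in Hz; must not exceed the Nyquist
#'   frequency `1/(2 dt)`.
#' @param duration_s series duration in seconds.
#' @param dt sampling interval in seconds (default 1 ms).
#' @param peak_to_peak nominal peak-to-peak modulation in intensity units;
#'   the series SD is `peak_to_peak/6`.
#' @param seed optional integer seed.
#' @return A `contrast_series` object: list with `values`, `dt`, `cutoff_hz`,
#'   `peak_to_peak`.
#' @export
make_bandlimited_gwn <- function(cutoff_hz, duration_s, dt = 0.001,
                                 peak_to_peak = 2, seed = NULL) {
  nyquist <- 1 / (2 * dt)
  if (cutoff_hz > nyquist + 1e-9) {
    stop("cutoff_hz (", cutoff_hz, " Hz) exceeds the Nyquist frequency (",
         nyquist, " Hz)")
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  maybe_set_seed(seed)
  n <- round(duration_s / dt)
  x <- rnorm(n)
  x <- brickwall_lowpass(x, dt, cutoff_hz)
  # the brick wall keeps a fraction cutoff/nyquist of white-noise power;
  # a deterministic gain restores SD = peak_to_peak/6 in expectation
  x <- x * sqrt(nyquist / cutoff_hz) * (peak_to_peak / 6)
  x <- x - mean(x)
  structure(list(values = x, dt = dt, cutoff_hz = cutoff_hz,
                 peak_to_peak = peak_to_peak),
            class = "contrast_series")
}

# Fourier-domain brick-wall low-pass (zeroes all bins strictly above cutoff)
brickwall_lowpass <- function(x, dt, cutoff_hz) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)   # two-sided frequency axis
  X <- fft(x)
  X[f > cutoff_hz + 1e-9] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Superimpose a contrast series on a background intensity
#'
#' Adds a constant background `BG` to a modulation series and clips the
#' result at zero (light intensity cannot be negative). Clipping at low
#' backgrounds turns symmetric Gaussian modulation into bursty, half-wave
#' rectified stimulation with prolonged dark intervals; the RMS contrast
#' `c = SD/mean` of the result is recorded. For `BG = 0` the analytic limit
#' is `c = sqrt(pi - 1) ~ 1.4633` irrespective of the modulation SD.
#'
#' @param series a `contrast_series`.
#' @param BG background intensity in the same relative units (>= 0).
#' @return A `light_series` object: list with `values` (>= 0), `dt`,
#'   `background`, `contrast`, `cutoff_hz`, `mean_photon_rate` (unset).
#' @export
apply_background <- function(series, BG) {
  stopifnot(inherits(series, "contrast_series"))
  if (BG < 0) stop("BG must be non-negative")
  v <- pmax(0, series$values + BG)
  m <- mean(v)
  light_series(v, series$dt, background = BG,
               contrast = if (m > 0) sd(v) / m else NA_real_,
               cutoff_hz = series$cutoff_hz)
}

#' Construct a light-intensity time series
#'
#' @param values non-negative relative intensities per bin.
#' @param dt sampling interval (s).
#' @param background background pedestal (intensity units).
#' @param contrast RMS contrast SD/mean; recomputed if `NULL`.
#' @param cutoff_hz optional stimulus bandwidth annotation.
#' @param mean_photon_rate optional calibrated mean absorbed photon rate.
#' @return A `light_series` object.
#' @export
light_series <- function(values, dt, background = NA_real_, contrast = NULL,
                         cutoff_hz = NA_real_, mean_photon_rate = NULL) {
  if (any(values < 0)) stop("light intensities must be non-negative")
  if (is.null(contrast)) {
    m <- mean(values)
    contrast <- if (m > 0) sd(values) / m else NA_real_
  }
  structure(list(values = as.numeric(values), dt = dt, background = background,
                 contrast = contrast, cutoff_hz = cutoff_hz,
                 mean_photon_rate = mean_photon_rate),
            class = "light_series")
}

#' @export
print.light_series <- function(x, ...) {
  cat(sprintf(
    "<light_series> %d bins x %.4g ms | BG %.3g | contrast %.3g\n",
    length(x$values), x$dt * 1000, x$background, x$contrast))
  invisible(x)
}

#' Burst / GWN stimulus for one grid condition
#'
#' Convenience wrapper: band-limited Gaussian modulation (2-unit nominal
#' peak-to-peak) superimposed on a background. The stimulus grid of the
#' encoding-gamut experiments crosses cutoffs {20, 50, 100, 200, 500} Hz
#' with backgrounds {0, 0.5, 1, 1.5}: low backgrounds clip the modulation
#' into high-contrast bursts, bright backgrounds leave it Gaussian.
#'
#' @inheritParams make_bandlimited_gwn
#' @param BG background intensity (relative units).
#' @return A `light_series`.
#' @export
burst_stimulus <- function(cutoff_hz, BG, duration_s = 2, dt = 0.001,
                           peak_to_peak = 2, seed = NULL) {
  apply_background(
    make_bandlimited_gwn(cutoff_hz, duration_s, dt, peak_to_peak, seed), BG)
}

#' Synthetic 1/f^n panoramic line scan
#'
#' Builds a circular (360 degree) one-dimensional intensity profile whose
#' amplitude spectrum follows `1/f^slope` with random phases, emulating the
#' second-order statistics of natural scenes. The profile is shifted and
#' scaled to the requested mean and RMS contrast and floored at a small
#' positive intensity.
#'
#' @param n_pixels number of azimuth pixels over \[0, 360) degrees (>= 64).
#' @param spectral_slope exponent n of the 1/f^n amplitude statistics.
#' @param mean_intensity mean intensity (relative units, > 0).
#' @param rms_contrast target SD/mean of the profile.
#' @param seed optional integer seed.
#' @return A `panorama` object: list with `intensity`, `n_pixels`,
#'   `spectral_slope`, `mean_intensity`, `rms_contrast`.
#' @export
synth_panorama <- function(n_pixels = 7200, spectral_slope = 1,
                           mean_intensity = 1, rms_contrast = 0.4,
                           seed = NULL) {
  if (n_pixels < 64) stop("n_pixels must be at least 64")
  if (mean_intensity <= 0) stop("mean_intensity must be positive")
  if (rms_contrast < 0) stop("rms_contrast must be non-negative")
  maybe_set_seed(seed)
  n <- as.integer(n_pixels)
  kmax <- floor((n - 1) / 2)
  amp <- (1:kmax)^(-spectral_slope)
  phase <- runif(kmax, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[2:(kmax + 1)] <- amp * exp(1i * phase)
  spec[n - (1:kmax) + 1] <- Conj(spec[2:(kmax + 1)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  if (rms_contrast > 0 && sd(x) > 0) {
    x <- x / sd(x) * (rms_contrast * mean_intensity)
  } else {
    x <- x * 0
  }
  x <- x + mean_intensity
  x <- pmax(x, 1e-3 * mean_intensity)
  structure(list(intensity = x, n_pixels = n, spectral_slope = spectral_slope,
                 mean_intensity = mean_intensity, rms_contrast = rms_contrast),
            class = "panorama")
}

# nearest-pixel circular lookup, azimuth in degrees
panorama_lookup <- function(pan, azimuth_deg) {
  n <- pan$n_pixels
  idx <- round(azimuth_deg / 360 * n) %% n
  pan$intensity[idx + 1]
}

#' Synthetic saccadic gaze trajectory
#'
#' Generates a yaw trace that alternates intersaccadic intervals with brief
#' saccades. Intersaccadic behavior mixes two bout types, as in walking
#' flies: quiet fixations (low-amplitude velocity jitter) and slower
#' drift/turning bouts (sustained sub-saccadic yaw while translating).
#' Saccades are raised-cosine velocity pulses with peak magnitude drawn
#' uniformly from `peak_velocity_range` and random sign (~1-5 saccades/s,
#' peak velocities 200-800 deg/s in walking flies), and are flagged with
#' the conventional |velocity| >= 200 deg/s criterion.
#'
#' @param duration_s trace duration (s).
#' @param saccade_rate_hz mean saccade rate (0-10 per second).
#' @param peak_velocity_range two-element range of peak saccade speed,
#'   inside \[200, 800\] deg/s.
#' @param fixation_jitter SD of the quiet-fixation velocity jitter (deg/s).
#' @param drift_speed_range magnitude range of drift/turning bout velocity
#'   (deg/s, below the saccade criterion).
#' @param drift_fraction fraction of intersaccadic time spent in
#'   drift/turning bouts.
#' @param bout_mean_s mean duration of one fixation or drift bout (s).
#' @param saccade_duration_s duration of one saccadic velocity pulse (s).
#' @param dt sampling interval (s).
#' @param seed optional integer seed.
#' @return A `walk_trace` object: list with `t`, `yaw` (deg), `velocity`
#'   (deg/s), `saccade_mask`, `dt`.
#' @export
synth_saccadic_walk <- function(duration_s, saccade_rate_hz = 3,
                                peak_velocity_range = c(200, 800),
                                fixation_jitter = 8,
                                drift_speed_range = c(60, 180),
                                drift_fraction = 0.65,
                                bout_mean_s = 0.3,
                                saccade_duration_s = 0.06,
                                dt = 0.001, seed = NULL) {
  if (saccade_rate_hz < 0 || saccade_rate_hz > 10) {
    stop("saccade_rate_hz must lie in [0, 10]")
  }
  if (peak_velocity_range[1] < 200 || peak_velocity_range[2] > 800 ||
      diff(peak_velocity_range) < 0) {
    stop("peak_velocity_range must be contained in [200, 800] deg/s")
  }
  maybe_set_seed(seed)
  n <- round(duration_s / dt)
  tt <- (seq_len(n) - 1) * dt
  # quiet-fixation jitter: band-limited (~5 Hz) Gaussian velocity noise,
  # kept safely below the 200 deg/s saccade criterion
  v <- rnorm(n)
  v <- brickwall_lowpass(v, dt, 5)
  if (sd(v) > 0) v <- v / sd(v) * fixation_jitter
  # drift/turning bouts: alternating exponential-length bouts, a fraction
  # of which carry sustained sub-saccadic yaw of random sign
  i <- 1L
  while (i <= n) {
    len <- max(1L, round(stats::rexp(1, 1 / bout_mean_s) / dt))
    j <- min(n, i + len - 1L)
    if (runif(1) < drift_fraction) {
      v[i:j] <- v[i:j] + runif(1, drift_speed_range[1], drift_speed_range[2]) *
        sample(c(-1, 1), 1)
    }
    i <- j + 1L
  }
  v <- pmin(pmax(v, -195), 195)
  npulse <- round(saccade_duration_s / dt)
  pulse_shape <- 0.5 * (1 - cos(2 * pi * (seq_len(npulse) - 0.5) / npulse))
  n_sac <- if (saccade_rate_hz > 0) rpois(1, saccade_rate_hz * duration_s) else 0L
  if (n_sac > 0) {
    onsets <- sort(sample.int(max(1L, n - npulse), n_sac, replace = TRUE))
    keep <- c(TRUE, diff(onsets) >= npulse)  # drop overlapping pulses
    onsets <- onsets[keep]
    for (o in onsets) {
      vp <- runif(1, peak_velocity_range[1], peak_velocity_range[2]) *
        sample(c(-1, 1), 1)
      idx <- o:(o + npulse - 1)
      v[idx] <- vp * pulse_shape
    }
  }
  yaw <- cumsum(v) * dt
  structure(list(t = tt, yaw = yaw, velocity = v,
                 saccade_mask = abs(v) >= 200, dt = dt),
            class = "walk_trace")
}

# number of distinct saccades detected by the >= 200 deg/s criterion
count_saccades <- function(walk) {
  m <- walk$saccade_mask
  sum(diff(c(FALSE, m)) == 1)
}

#' Light input from a gaze trajectory over a panorama
#'
#' Reads intensity from a circular panorama along a yaw trajectory
#' (nearest-pixel lookup with wrap-around). Three viewing modes are
#' supported: `saccadic` uses the walk's own yaw; `linear_median`
#' integrates a constant velocity equal to the median of |velocity|;
#' `shuffled` permutes the per-sample velocity sequence before
#' integrating (preserving the total displacement).
#'
#' @param panorama a `panorama`.
#' @param walk a `walk_trace`.
#' @param mode one of `"saccadic"`, `"linear_median"`, `"shuffled"`.
#' @param dt output sampling interval (s); the walk is linearly resampled
#'   if it differs.
#' @param seed seed for the shuffled-mode permutation.
#' @return A `light_series`.
#' @export
walk_to_light_series <- function(panorama, walk,
                                 mode = c("saccadic", "linear_median",
                                          "shuffled"),
                                 dt = 0.001, seed = NULL) {
  mode <- match.arg(mode)
  if (length(walk$yaw) == 0) stop("empty walk trace")
  yaw <- switch(mode,
    saccadic = walk$yaw,
    linear_median = median(abs(walk$velocity)) * walk$t,
    shuffled = {
      maybe_set_seed(seed)
      cumsum(sample(walk$velocity)) * walk$dt
    })
  if (abs(dt - walk$dt) > 1e-12) {
    t_out <- seq(0, walk$t[length(walk$t)], by = dt)
    yaw <- stats::approx(walk$t, yaw, xout = t_out, rule = 2)$y
  }
  v <- panorama_lookup(panorama, yaw)
  light_series(v, dt, background = panorama$mean_intensity)
}

#' First-derivative histogram statistics of a light series
#'
#' Normalizes the series to unit maximum, takes first differences, and bins
#' them on a symmetric axis over \[-1, 1\]. Sparse, bursty series (saccadic
#' viewing) concentrate mass at zero (fixations) and in the tails
#' (saccades), raising both the peak count and the kurtosis relative to
#' constant-velocity viewing.
#'
#' @param series a `light_series`.
#' @param n_bins number of histogram bins (default 201).
#' @return List with `breaks`, `counts`, `peak_count`, `kurtosis` (standard
#'   fourth-moment kurtosis, normal = 3; `NA` and `degenerate = TRUE` for a
#'   constant series).
#' @export
derivative_stats <- function(series, n_bins = 201) {
  v <- series$values
  if (length(v) < 3) stop("series too short for derivative statistics")
  mx <- max(v)
  d <- if (mx > 0) diff(v / mx) else diff(v)
  degenerate <- var(d) == 0
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  d_clamped <- pmin(pmax(d, -1), 1)
  counts <- graphics::hist(d_clamped, breaks = breaks, plot = FALSE)$counts
  kur <- if (degenerate) NA_real_ else mean((d - mean(d))^4) / var(d)^2
  list(breaks = breaks, counts = counts, peak_count = max(counts),
       kurtosis = kur, degenerate = degenerate,
       convention = "fourth standardized moment; normal = 3")
}

#' Poisson photon stream from a light series
#'
#' Draws independent repeated trials of per-bin photon counts from an
#' inhomogeneous Poisson law with rate proportional to the light intensity,
#' scaled so the time-averaged absorbed rate equals `mean_rate`.
#'
#' @param series a `light_series` with non-zero mean intensity.
#' @param mean_rate time-averaged absorbed photon rate (photons/s, > 0).
#' @param n_trials number of independent trials.
#' @param seed optional integer seed.
#' @return A `photon_stream` object: list with `counts` (trials x bins
#'   integer matrix), `dt`, `mean_rate`, `rate` (photons/s per bin).
#' @export
poisson_photon_stream <- function(series, mean_rate, n_trials = 20,
                                  seed = NULL) {
  if (mean_rate <= 0) stop("mean_rate must be positive")
  m <- mean(series$values)
  if (m <= 0) stop("light series has zero mean intensity; cannot scale rate")
  maybe_set_seed(seed)
  rate <- series$values / m * mean_rate
  nb <- length(rate)
  counts <- matrix(rpois(n_trials * nb, rep(rate * series$dt, each = n_trials)),
                   nrow = n_trials)
  structure(list(counts = counts, dt = series$dt, mean_rate = mean_rate,
                 rate = rate),
            class = "photon_stream")
}
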