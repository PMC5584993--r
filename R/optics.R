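#' Gaussian receptive field
#'
#' Angular sensitivity profile of a photoreceptor: a Gaussian over azimuth
#' with acceptance angle `delta_rho` (full width at half maximum) and unit
#' integral, so that a spatially uniform scene of intensity I yields light
#' input I.
#'
#' @param delta_rho acceptance angle (FWHM) in degrees, > 0.
#' @param center receptive-field center azimuth in degrees.
#' @return A `receptive_field`: list with `center`, `delta_rho`, `sigma`.
#' @export
gaussian_rf <- function(delta_rho, center = 0) {
  if (delta_rho <= 0) stop("delta_rho must be positive")
  structure(list(center = center, delta_rho = delta_rho,
                 sigma = delta_rho / sqrt(8 * log(2))),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> center %.2f deg | delta_rho %.2f deg\n",
              x$center, x$delta_rho))
  invisible(x)
}

# sensitivity profile (unit integral) at azimuths `az`
rf_profile <- function(rf, az) dnorm(az, rf$center, rf$sigma)

#' Moving two-dot scene
#'
#' Two bright dots (1.7 degree top-hat profiles by default) travel rigidly
#' at constant speed across the visual field, front-to-back (+azimuth) or
#' back-to-front. The trajectory spans `span` degrees on both sides of
#' azimuth 0 (the resting receptive-field center); dot intensities add
#' where they overlap, on top of a uniform background.
#'
#' @param separation center-to-center dot separation (deg).
#' @param speed crossing speed (deg/s, > 0).
#' @param dot_size dot width (deg, default 1.7).
#' @param direction `"front_to_back"` or `"back_to_front"`.
#' @param dot_intensity intensity of each dot (relative units).
#' @param background uniform background intensity.
#' @param span half-extent of the traverse around azimuth 0 (deg).
#' @return A `moving_dot_scene`.
#' @export
moving_dot_scene <- function(separation, speed, dot_size = 1.7,
                             direction = c("front_to_back", "back_to_front"),
                             dot_intensity = 1, background = 0, span = 15) {
  direction <- match.arg(direction)
  stopifnot(speed > 0, separation >= 0, dot_size > 0)
  structure(list(separation = separation, speed = speed, dot_size = dot_size,
                 direction = direction, dot_intensity = dot_intensity,
                 background = background, span = span,
                 duration_s = (2 * span + separation) / speed),
            class = "moving_dot_scene")
}

# dot-center azimuths at time t (columns: one per dot)
dot_positions <- function(scene, t) {
  s <- if (scene$direction == "front_to_back") 1 else -1
  # the dot pair midpoint sweeps from -span-sep/2 to +span+sep/2 (times s)
  m <- s * (-(scene$span + scene$separation / 2) + scene$speed * t)
  cbind(m - s * scene$separation / 2, m + s * scene$separation / 2)
}

# light collected by a Gaussian RF (center c, sd sigma) from the scene at
# time t: analytic top-hat x Gaussian overlap integrals
scene_light <- function(scene, t, center, sigma) {
  p <- dot_positions(scene, t)
  hw <- scene$dot_size / 2
  li <- scene$dot_intensity *
    (pnorm((p + hw - center) / sigma) - pnorm((p - hw - center) / sigma))
  scene$background + rowSums(li)
}

#' Light input through a static receptive field
#'
#' Per-bin spatial integral of the moving scene against a fixed Gaussian
#' receptive field; the classic (immobile-rhabdomere) light input.
#'
#' @param rf a `receptive_field`.
#' @param scene a `moving_dot_scene`.
#' @param dt sampling interval (s).
#' @return A `light_series` covering the scene traverse.
#' @export
static_light_input <- function(rf, scene, dt = 0.001) {
  tt <- seq(0, scene$duration_s, by = dt)
  v <- scene_light(scene, tt, rf$center, rf$sigma)
  light_series(v, dt, background = scene$background)
}

#' Synthetic photoreceptor impulse response
#'
#' Log-normal temporal kernel used by the classic Volterra prediction
#' (cell-specific measured kernels are not part of this package). Causal
#' and normalized to unit integral.
#'
#' @param t_peak_s kernel time-to-peak (s).
#' @param sigma_log log-domain width.
#' @param duration_s kernel support (s).
#' @param dt sampling interval (s).
#' @return An `impulse_response`: list with `kernel`, `dt`.
#' @export
impulse_response <- function(t_peak_s = 0.015, sigma_log = 0.35,
                             duration_s = 0.1, dt = 0.001) {
  tt <- seq(dt, duration_s, by = dt)
  mu <- log(t_peak_s) + sigma_log^2   # mode at t_peak
  k <- stats::dlnorm(tt, mu, sigma_log)
  k <- c(0, k / sum(k))
  structure(list(kernel = k, dt = dt), class = "impulse_response")
}

#' Classic Volterra motion-blur prediction
#'
#' Convolves the static receptive-field light input of a moving scene with
#' a causal temporal impulse response (first Volterra kernel): the classic
#' deterministic prediction of photoreceptor output to moving objects.
#'
#' @param rf a `receptive_field`.
#' @param kernel an `impulse_response`.
#' @param scene a `moving_dot_scene`.
#' @param dt sampling interval (s).
#' @return A numeric predicted-response series.
#' @export
volterra_predict <- function(rf, kernel, scene, dt = 0.001) {
  x <- static_light_input(rf, scene, dt)$values
  k <- kernel$kernel
  nh <- length(k)
  out <- stats::filter(c(numeric(nh), x), k, method = "convolution", sides = 1)
  as.numeric(out[nh + seq_along(x)])
}

#' Two-point Rayleigh resolvability of a response trace
#'
#' Locates the two largest local maxima of the (lightly smoothed) trace and
#' the minimum between them; the percent dip is
#' `D = 100 (min(P1, P2) - T) / min(P1, P2)`. The trace is resolved when
#' two maxima exist and `D` exceeds the noise floor.
#'
#' @param y numeric response series.
#' @param dt sampling interval (s).
#' @param smooth_ms moving-average smoothing width (ms; 0 disables).
#' @param noise_floor minimal percent dip counted as resolved (default 1).
#' @param min_peak_frac minimal height of a counted local maximum,
#'   relative to the trace maximum (default 0.2): low shoulders and noise
#'   ripples are not treated as object peaks.
#' @return A `resolvability`: list with `P1`, `P2`, `trough`, `D` (percent),
#'   `resolved`, `peak_times_s`.
#' @export
rayleigh_resolvability <- function(y, dt = 0.001, smooth_ms = 5,
                                   noise_floor = 1, min_peak_frac = 0.2) {
  ys <- if (smooth_ms > 0) moving_average(y, round(smooth_ms / (dt * 1000)))
        else y
  n <- length(ys)
  unresolved <- list(P1 = max(ys), P2 = NA_real_, trough = NA_real_, D = 0,
                     resolved = FALSE, peak_times_s = numeric(0))
  if (n < 3) return(structure(unresolved, class = "resolvability"))
  d <- diff(ys)
  # local maxima: rising-to-falling sign changes of the derivative
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  pk <- which(diff(sgn) < 0) + 1L
  pk <- pk[ys[pk] >= min_peak_frac * max(ys)]
  if (length(pk) < 2) return(structure(unresolved, class = "resolvability"))
  top2 <- pk[order(ys[pk], decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  P1 <- ys[top2[1]]; P2 <- ys[top2[2]]
  trough <- min(ys[top2[1]:top2[2]])
  Pmin <- min(P1, P2)
  D <- if (Pmin > 0) 100 * (Pmin - trough) / Pmin else 0
  structure(list(P1 = P1, P2 = P2, trough = trough, D = D,
                 resolved = D > noise_floor,
                 peak_times_s = (top2 - 1) * dt),
            class = "resolvability")
}

#' @export
print.resolvability <- function(x, ...) {
  cat(sprintf("<resolvability> D = %.1f%% (%s)\n", x$D,
              if (x$resolved) "resolved" else "unresolved"))
  invisible(x)
}

# closed-form percent dip of the sum of two unit Gaussians (sd sigma)
# separated by s: D = 100 (1 - 2 exp(-s^2/8 sigma^2) / (1 + exp(-s^2/2 sigma^2)))
two_gaussian_dip <- function(s, sigma) {
  peak <- 1 + exp(-s^2 / (2 * sigma^2))
  mid <- 2 * exp(-s^2 / (8 * sigma^2))
  100 * max(0, 1 - mid / peak)
}

#' Half-maximum crossing times of a response trace
#'
#' Times (s) at which a lightly smoothed trace first rises above and last
#' falls below half of its maximum; used to quantify the phasic
#' direction-selectivity of responses to opposing motion directions.
#'
#' @param y numeric response series.
#' @param dt sampling interval (s).
#' @param smooth_ms moving-average smoothing (ms).
#' @return Named numeric vector `c(rise, fall)` in seconds.
#' @export
half_max_times <- function(y, dt = 0.001, smooth_ms = 5) {
  ys <- moving_average(y, round(smooth_ms / (dt * 1000)))
  hm <- max(ys) / 2
  above <- which(ys >= hm)
  c(rise = (above[1] - 1) * dt, fall = (above[length(above)] - 1) * dt)
}
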