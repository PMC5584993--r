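#' Microsaccadic receptive-field kinetics
#'
#' Photomechanical rhabdomere contraction: light drives a lateral
#' rhabdomere displacement (and, via the fixed ommatidium optics, a
#' receptive-field shift in the front-to-back direction) and a concurrent
#' narrowing of the acceptance angle. The displacement follows a delayed
#' rise/adapt linear kinetic (fast activation low-pass, slower adaptation
#' stage) driven by a saturating logarithmic function of the instantaneous
#' light input; a sustained step displaces maximally 70-200 ms after
#' onset and then partially returns. The amplitude law is calibrated to
#' the observed 0.2-1.2 um displacement range, converted to degrees at
#' 3.33 deg/um, and the acceptance angle narrows linearly with normalized
#' displacement from `delta_rho_rest` to `delta_rho_contracted`.
#'
#' @param latency_s activation delay (s; observed range 8-20 ms).
#' @param tau_rise_s activation time constant of the contraction (s).
#' @param tau_return_s release time constant of the activation stage (s):
#'   a brief photon surge commits a contraction that outlives it,
#'   returning more slowly than it built up.
#' @param tau_adapt_s adaptation time constant (s; subtractive stage that
#'   removes sustained displacement).
#' @param adapt_frac fraction of the displacement removed by adaptation at
#'   steady state (0 = no adaptation).
#' @param max_displacement_um saturating displacement (um; observed max 1.2).
#' @param i_half light input (relative units) producing half the
#'   log-saturation scale.
#' @param i_sat light input treated as saturating.
#' @param um_to_deg optical conversion, degrees of receptive-field shift
#'   per um of rhabdomere displacement (default 3.33, from the printed
#'   0.2-1.2 um <-> 0.5-4.0 deg pairing).
#' @param delta_rho_rest,delta_rho_contracted resting and fully contracted
#'   acceptance angles (deg; defaults 8.1 and 4.0).
#' @param direction receptive-field movement direction
#'   (`"front_to_back"`, the lens-inverted image of the rhabdomere's
#'   back-to-front motion).
#' @return A `microsaccade_kinetics` object.
#' @export
microsaccade_kinetics <- function(latency_s = 0.020,
                                  tau_rise_s = 0.025,
                                  tau_return_s = 0.100,
                                  tau_adapt_s = 0.300,
                                  adapt_frac = 1,
                                  max_displacement_um = 1.2,
                                  i_half = 0.04,
                                  i_sat = 0.10,
                                  um_to_deg = 3.33,
                                  delta_rho_rest = 8.1,
                                  delta_rho_contracted = 4.0,
                                  direction = "front_to_back") {
  stopifnot(latency_s >= 0, tau_rise_s > 0, tau_return_s > 0,
            tau_adapt_s > 0,
            adapt_frac >= 0, adapt_frac <= 1,
            max_displacement_um >= 0,
            delta_rho_contracted > 0,
            delta_rho_rest >= delta_rho_contracted)
  structure(list(latency_s = latency_s, tau_rise_s = tau_rise_s,
                 tau_return_s = tau_return_s,
                 tau_adapt_s = tau_adapt_s, adapt_frac = adapt_frac,
                 max_displacement_um = max_displacement_um,
                 i_half = i_half, i_sat = i_sat, um_to_deg = um_to_deg,
                 delta_rho_rest = delta_rho_rest,
                 delta_rho_contracted = delta_rho_contracted,
                 direction = direction),
            class = "microsaccade_kinetics")
}

# saturating logarithmic amplitude law, normalized to [0, 1]: zero below
# the threshold intensity i_half, rising as log10(I / i_half) and clamped
# at the saturating intensity i_sat (equal-decade steps give equal
# displacement increments, the hallmark of the measured log-sensitivity)
log_amplitude <- function(I, kin) {
  u <- log10(pmax(I, 1e-12) / kin$i_half) / log10(kin$i_sat / kin$i_half)
  # u = 1 at i_sat; brighter input overdrives the stage further (the
  # displacement itself is clamped at max_displacement_um downstream), so
  # brief bright inputs still commit full-scale contractions
  pmax(0, u)
}

# peak of the unit-step response of the rise/adapt cascade (for kernel
# normalization so that a saturating step reaches max_displacement_um)
step_response_peak <- function(kin, dt = 0.001, horizon_s = 1.5) {
  n <- round(horizon_s / dt)
  s1 <- s2 <- 0
  pk <- 0
  a1 <- dt / kin$tau_rise_s
  a1r <- dt / kin$tau_return_s
  a2 <- dt / kin$tau_adapt_s
  for (i in seq_len(n)) {
    s2 <- s2 + a2 * (1 - s2)
    drv <- max(0, 1 - kin$adapt_frac * s2)
    s1 <- s1 + (if (drv >= s1) a1 else a1r) * (drv - s1)
    pk <- max(pk, s1)
  }
  pk
}

#' Displacement and acceptance-angle dynamics driven by a light input
#'
#' Runs the microsaccade kinetics open-loop on a given light-input series:
#' the delayed, log-saturated drive passes a fast activation stage and a
#' slower subtractive adaptation stage; the (non-negative) output is
#' scaled so that a saturating step peaks at `max_displacement_um`.
#'
#' @param light numeric light-input series (relative units) or a
#'   `light_series`.
#' @param kinetics a `microsaccade_kinetics`.
#' @param dt sampling interval (s).
#' @return List with `displacement_um`, `center_shift_deg` (signed:
#'   positive = front-to-back), `delta_rho_deg`.
#' @export
microsaccade_displacement <- function(light, kinetics, dt = 0.001) {
  v <- if (inherits(light, "light_series")) light$values else as.numeric(light)
  kin <- kinetics
  u <- log_amplitude(v, kin)
  nd <- round(kin$latency_s / dt)
  u <- c(numeric(nd), u)[seq_along(v)]
  a1 <- dt / kin$tau_rise_s
  a1r <- dt / kin$tau_return_s
  a2 <- dt / kin$tau_adapt_s
  s1 <- s2 <- 0
  d <- numeric(length(v))
  for (i in seq_along(v)) {
    # a slow subtractive stage adapts the drive (gradual intensity ramps
    # produce little net drive), and the activation stage has a fast
    # attack and a slow release: a brief photon surge commits a
    # contraction that then runs its course
    s2 <- s2 + a2 * (u[i] - s2)
    drv <- max(0, u[i] - kin$adapt_frac * s2)
    s1 <- s1 + (if (drv >= s1) a1 else a1r) * (drv - s1)
    d[i] <- s1
  }
  d_um <- d / step_response_peak(kin, dt) * kin$max_displacement_um
  d_um <- pmin(d_um, kin$max_displacement_um)
  sgn <- if (kin$direction == "front_to_back") 1 else -1
  dn <- if (kin$max_displacement_um > 0) d_um / kin$max_displacement_um else d_um
  list(displacement_um = d_um,
       center_shift_deg = sgn * kin$um_to_deg * d_um,
       delta_rho_deg = kin$delta_rho_rest -
         (kin$delta_rho_rest - kin$delta_rho_contracted) * dn)
}

#' Light input through a microsaccadic (moving, narrowing) receptive field
#'
#' Per-step closed loop: the current light input drives the contraction
#' kinetics, and the displaced, narrowed receptive field samples the scene
#' at the next step (one-step-lag feedback). With zero-amplitude kinetics
#' this reduces exactly to [static_light_input()].
#'
#' @param scene a `moving_dot_scene`.
#' @param rf resting `receptive_field`.
#' @param kinetics a `microsaccade_kinetics`.
#' @param dt sampling interval (s; <= 1 ms for loop stability).
#' @return A `light_series` with attributes `center_deg` and
#'   `delta_rho_deg` (the receptive-field trajectory).
#' @export
microsaccadic_light_input <- function(scene, rf, kinetics, dt = 0.001) {
  if (dt > 0.001 + 1e-12) stop("dt must be <= 1 ms for the feedback loop")
  kin <- kinetics
  tt <- seq(0, scene$duration_s, by = dt)
  n <- length(tt)
  nd <- max(0L, round(kin$latency_s / dt))
  a1 <- dt / kin$tau_rise_s
  a1r <- dt / kin$tau_return_s
  a2 <- dt / kin$tau_adapt_s
  norm <- step_response_peak(kin, dt)
  sgn <- if (kin$direction == "front_to_back") 1 else -1
  fwhm2sig <- sqrt(8 * log(2))
  ubuf <- numeric(n + nd)
  s1 <- s2 <- 0
  v <- center <- drho <- numeric(n)
  cen <- rf$center
  sig_rest <- rf$delta_rho / fwhm2sig
  sig <- sig_rest
  for (i in seq_len(n)) {
    # contraction retracts the rhabdomere from the focal point: the
    # acceptance angle narrows and the captured light shrinks with it
    # (peak angular sensitivity held, area proportional to delta_rho)
    v[i] <- scene_light(scene, tt[i], cen, sig) * (sig / sig_rest)
    center[i] <- cen
    drho[i] <- sig * fwhm2sig
    ubuf[i + nd] <- log_amplitude(v[i], kin)
    s2 <- s2 + a2 * (ubuf[i] - s2)
    drv <- max(0, ubuf[i] - kin$adapt_frac * s2)
    s1 <- s1 + (if (drv >= s1) a1 else a1r) * (drv - s1)
    d_um <- min(s1 / norm, 1) * kin$max_displacement_um
    dn <- if (kin$max_displacement_um > 0) d_um / kin$max_displacement_um
          else 0
    cen <- rf$center + sgn * kin$um_to_deg * d_um
    # the resting width is the supplied receptive field's; narrowing
    # interpolates linearly towards the contracted acceptance angle
    sig <- (rf$delta_rho -
              (rf$delta_rho - kin$delta_rho_contracted) * dn) / fwhm2sig
  }
  out <- light_series(v, dt, background = scene$background)
  attr(out, "center_deg") <- center
  attr(out, "delta_rho_deg") <- drho
  out
}

#' Simulate photoreceptor output to a moving scene and score resolvability
#'
#' Full spatiotemporal chain: microsaccadic (or, with `NULL` kinetics,
#' static) light input -> refractory photon sampling -> mean response ->
#' Rayleigh resolvability of the mean trace.
#'
#' @param scene a `moving_dot_scene`.
#' @param rf resting `receptive_field`.
#' @param kinetics a `microsaccade_kinetics`, or `NULL` for the static
#'   (classic) receptive field.
#' @param params a `sampling_params`.
#' @param photons_per_unit absorbed photon rate per unit light input
#'   (photons/s).
#' @param n_trials number of stochastic trials.
#' @param seed optional master seed.
#' @param smooth_ms smoothing for peak detection (ms); `NULL` scales the
#'   window with the traverse duration (1.5%, clamped to 5-50 ms) so slow
#'   crossings are judged on the same relative timescale as fast ones.
#' @param noise_floor passed to [rayleigh_resolvability()].
#' @param dt sampling interval (s).
#' @return List with `resolvability`, `ensemble`, `light` (the light-input
#'   series).
#' @export
simulate_acuity <- function(scene, rf, kinetics, params = sampling_params(),
                            photons_per_unit = 3e6, n_trials = 6,
                            seed = NULL, smooth_ms = NULL, noise_floor = 1,
                            dt = 0.001) {
  if (is.null(smooth_ms)) {
    smooth_ms <- min(50, max(5, 1000 * 0.015 * scene$duration_s))
  }
  light <- if (is.null(kinetics)) static_light_input(rf, scene, dt)
           else microsaccadic_light_input(scene, rf, kinetics, dt)
  rate <- light$values * photons_per_unit
  ens <- simulate_ensemble_rates(rate, dt, params, n_trials, seed,
                                 provenance = list(
                                   separation = scene$separation,
                                   speed = scene$speed, seed = seed))
  ybar <- colMeans(ens$y)
  # data-driven noise floor: photon noise surviving the trial average can
  # carve percent-scale dips into a fused response. The trial-to-trial SD
  # of the smoothed traces estimates the standard error of the smoothed
  # mean, and the floor is raised to the scale of noise-induced dips
  # (4 x that standard error, relative to the response peak)
  w <- max(1L, round(smooth_ms / (dt * 1000)))
  ys <- moving_average(ybar, w)
  ysm <- t(apply(ens$y, 1, moving_average, width = w))
  se_bin <- apply(ysm, 2, sd) / sqrt(nrow(ysm))
  hi <- ys > 0.2 * max(ys)
  se <- if (any(hi)) mean(se_bin[hi]) else 0
  # a noise dip is an extreme excursion over the many correlation lengths
  # of a long trace, hence the extreme-value factor sqrt(2 log n_eff)
  n_eff <- max(2, length(ys) / max(w, 8))
  evf <- 2 * sqrt(2 * log(n_eff))
  eff_floor <- max(noise_floor,
                   if (max(ys) > 0) 100 * evf * se / max(ys) else noise_floor)
  res <- rayleigh_resolvability(ybar, dt, smooth_ms = smooth_ms,
                                noise_floor = eff_floor)
  res$noise_floor <- eff_floor
  list(resolvability = res, ensemble = ens, light = light)
}

#' Rayleigh-resolvability map over dot separations and crossing speeds
#'
#' Runs one seeded [simulate_acuity()] per (separation, speed) grid cell
#' and collects the percent dip `D` and the resolved mask: the hyperacuity
#' heat map.
#'
#' @param separations dot separations (deg).
#' @param speeds crossing speeds (deg/s).
#' @param rf resting `receptive_field`.
#' @param kinetics a `microsaccade_kinetics` (or `NULL` for the static
#'   model).
#' @param params a `sampling_params`.
#' @param seed master seed; each cell gets a deterministic child seed.
#' @param ... passed to [simulate_acuity()].
#' @return A `resolvability_map`: data.frame with `separation`, `speed`,
#'   `D`, `resolved`.
#' @export
resolvability_heatmap <- function(separations = 1:4,
                                  speeds = c(2.5, 5, 10, 25, 50, 100, 200, 300),
                                  rf = gaussian_rf(8.1),
                                  kinetics = microsaccade_kinetics(),
                                  params = sampling_params(),
                                  seed = NULL, ...) {
  stopifnot(length(separations) > 0, length(speeds) > 0)
  grid <- expand.grid(separation = separations, speed = speeds)
  seeds <- child_seeds(seed, nrow(grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    scene <- moving_dot_scene(grid$separation[i], grid$speed[i])
    simulate_acuity(scene, rf, kinetics, params, seed = seeds[[i]],
                    ...)$resolvability
  })
  grid$D <- vapply(res, `[[`, numeric(1), "D")
  grid$resolved <- vapply(res, `[[`, logical(1), "resolved")
  class(grid) <- c("resolvability_map", class(grid))
  grid
}
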