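#' Split a response ensemble into signal and noise
#'
#' The signal is the across-trial mean at every bin; each trial's noise
#' trace is its difference from the signal. Noise traces therefore sum to
#' zero at every bin.
#'
#' @param ensemble a `response_ensemble` with at least 2 trials.
#' @return List with `signal` (numeric vector) and `noise` (trials x bins
#'   matrix).
#' @export
split_signal_noise <- function(ensemble) {
  y <- ensemble$y
  if (nrow(y) < 2) stop("noise is undefined for a single trial")
  s <- colMeans(y)
  list(signal = s, noise = sweep(y, 2, s))
}

# Blackman-Harris 4-term window (standard coefficient set)
blackman_harris4 <- function(n) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- 2 * pi * (seq_len(n) - 1) / (n - 1)
  a[1] - a[2] * cos(k) + a[3] * cos(2 * k) - a[4] * cos(3 * k)
}

# one-sided windowed periodogram, power corrected for the window gain
windowed_periodogram <- function(x, w, fs) {
  n <- length(x)
  X <- fft(x * w)
  p <- Mod(X[seq_len(n / 2 + 1)])^2 / (sum(w^2) * fs)
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]
  p
}

# segment start indices for length-`win` windows with the given stride
segment_starts <- function(n, win, stride) {
  if (n < win) return(integer(0))
  seq(1L, n - win + 1L, by = stride)
}

#' Signal-to-noise ratio spectrum of a response ensemble
#'
#' The ensemble is split into a signal (trial mean) and per-trial noise
#' traces. Each trace is segmented into 500-point stretches, windowed with
#' a 4-term Blackman-Harris window, and the averaged windowed periodograms
#' give the signal and noise power spectra; `SNR(f)` is their elementwise
#' ratio. The signal trace is segmented with 50% overlap (stride 250); the
#' noise traces use stride 750, three segments per 2000-point trace, so a
#' 20 x 2000 ensemble yields 7 signal and 60 noise spectral segments.
#'
#' @param ensemble a `response_ensemble` (traces >= 500 points at 1 kHz).
#' @param window_points spectral window length (default 500).
#' @param snr_cap cap applied where noise power underflows (default 1e7);
#'   capping is flagged with a warning instead of returning infinities.
#' @return A `spectral_estimate`: list with `frequencies`, `signal_power`,
#'   `noise_power`, `snr`, `n_signal_segments`, `n_noise_segments`,
#'   `degenerate_noise` flag.
#' @export
snr_spectrum <- function(ensemble, window_points = 500, snr_cap = 1e7) {
  dt <- ensemble$dt
  fs <- 1 / dt
  L <- ncol(ensemble$y)
  if (L < window_points) {
    stop("traces shorter than the ", window_points, "-point spectral window")
  }
  sn <- split_signal_noise(ensemble)
  w <- blackman_harris4(window_points)
  sig_starts <- segment_starts(L, window_points, window_points %/% 2)
  noi_starts <- segment_starts(L, window_points, (window_points * 3L) %/% 2L)
  sig_p <- rowMeans(vapply(sig_starts, function(s0) {
    windowed_periodogram(sn$signal[s0:(s0 + window_points - 1)], w, fs)
  }, numeric(window_points / 2 + 1)))
  noi_acc <- matrix(0, window_points / 2 + 1, 0)
  noi_p <- rowMeans(vapply(seq_len(nrow(sn$noise)), function(i) {
    rowMeans(vapply(noi_starts, function(s0) {
      windowed_periodogram(sn$noise[i, s0:(s0 + window_points - 1)], w, fs)
    }, numeric(window_points / 2 + 1)))
  }, numeric(window_points / 2 + 1)))
  degenerate <- any(noi_p <= 0)
  if (degenerate) {
    warning("zero noise power at some frequencies; SNR capped at ", snr_cap)
  }
  snr <- ifelse(noi_p > 0, sig_p / noi_p, snr_cap)
  snr <- pmin(snr, snr_cap)
  structure(list(frequencies = (0:(window_points / 2)) * fs / window_points,
                 signal_power = sig_p, noise_power = noi_p, snr = snr,
                 window = "Blackman-Harris 4-term",
                 n_signal_segments = length(sig_starts),
                 n_noise_segments = length(noi_starts) * nrow(sn$noise),
                 degenerate_noise = degenerate),
            class = "spectral_estimate")
}

#' Shannon information rate from an SNR spectrum
#'
#' `R = integral of log2(SNR(f) + 1) df` over the analysis band,
#' trapezoidal integration on the spectral grid. The band defaults to
#' 2-500 Hz (1 kHz sampling, 500-point window).
#'
#' @param spec a `spectral_estimate`.
#' @param f_min,f_max integration band (Hz).
#' @return An `info_rate`: list with `R` (bits/s), `method`, `band`.
#' @export
shannon_rate <- function(spec, f_min = 2, f_max = 500) {
  f <- spec$frequencies
  keep <- f >= f_min - 1e-9 & f <= f_max + 1e-9
  if (!any(keep)) stop("empty integration band")
  structure(list(R = trapz(f[keep], log2(spec$snr[keep] + 1)),
                 method = "shannon", band = c(f_min, f_max)),
            class = "info_rate")
}

#' Chunked Shannon rate (mean and SD over data chunks)
#'
#' Estimates the Shannon rate from `n_chunks` equal-length chunks of the
#' ensemble (default: eleven 1000-point chunks with 100-point shifts on a
#' 2000-point trace) and reports their mean and SD.
#'
#' @param ensemble a `response_ensemble`.
#' @param chunk_points chunk length in bins.
#' @param n_chunks number of chunks.
#' @param ... passed to [shannon_rate()].
#' @return An `info_rate` with `R` (mean over chunks), `R_sd`, `R_chunks`.
#' @export
shannon_rate_chunked <- function(ensemble, chunk_points = 1000, n_chunks = 11,
                                 ...) {
  L <- ncol(ensemble$y)
  stopifnot(L >= chunk_points)
  starts <- if (n_chunks == 1) 1 else
    round(seq(1, L - chunk_points + 1, length.out = n_chunks))
  rs <- vapply(starts, function(s0) {
    sub <- response_ensemble(ensemble$y[, s0:(s0 + chunk_points - 1)],
                             ensemble$dt)
    shannon_rate(snr_spectrum(sub), ...)$R
  }, numeric(1))
  structure(list(R = mean(rs), R_sd = sd(rs), R_chunks = rs,
                 method = "shannon_chunked"),
            class = "info_rate")
}

# quantize an ensemble into nu equal-width levels over its amplitude range;
# ties at bin edges go to the lower bin
quantize_ensemble <- function(y, nu) {
  lo <- min(y); hi <- max(y)
  if (hi <= lo) return(matrix(1L, nrow(y), ncol(y)))
  w <- (hi - lo) / nu
  q <- ceiling((y - lo) / w)
  q[q < 1L] <- 1L
  q[q > nu] <- nu
  matrix(as.integer(q), nrow(y))
}

# encode words of `L` letters at sliding (stride-1) positions: returns a
# trials x positions matrix of word codes. Sliding words use every letter
# of the limited data at every word length, reducing undersampling bias of
# the entropy estimates.
encode_words <- function(q, L, nu) {
  P <- ncol(q) - L + 1L
  e <- matrix(0, nrow(q), P)
  for (k in seq_len(L)) {
    e <- e + q[, k:(k + P - 1L), drop = FALSE] * nu^(k - 1)
  }
  e
}

entropy_bits <- function(v) {
  cnt <- tabulate(match(v, unique(v)))
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

#' Word entropies of a quantized response ensemble
#'
#' Responses are linearly quantized into `nu` levels over the ensemble
#' amplitude range and cut into non-overlapping words of `Tw_letters`
#' letters of duration `t_w`. The total entropy `H_S` comes from the pooled
#' word distribution (over trials and word positions); the noise entropy
#' `H_N` is the across-trial word entropy at each time-locked position,
#' averaged over positions. The data-size fraction restricts the number of
#' trials used.
#'
#' @param ensemble a `response_ensemble`.
#' @param nu number of quantization levels (>= 1).
#' @param Tw_letters word length in letters.
#' @param size_fraction fraction of trials used, in (0, 1\].
#' @param t_w letter duration in seconds (default 1 ms; must equal the
#'   ensemble bin width).
#' @return List with `H_S`, `H_N` (bits per word), `Tw_s` (word duration,
#'   s), `nu`, `n_trials_used`.
#' @export
word_entropies <- function(ensemble, nu, Tw_letters, size_fraction = 1,
                           t_w = 0.001) {
  if (nu < 1) stop("nu must be at least 1")
  stopifnot(size_fraction > 0, size_fraction <= 1)
  if (abs(t_w - ensemble$dt) > 1e-12) {
    stop("letter duration must equal the ensemble bin width")
  }
  q <- quantize_ensemble(ensemble$y, nu)
  e <- encode_words(q, Tw_letters, nu)
  m <- max(2L, round(size_fraction * nrow(e)))
  e <- e[seq_len(m), , drop = FALSE]
  H_S <- entropy_bits(as.vector(e))
  H_N <- mean(apply(e, 2, entropy_bits))
  list(H_S = H_S, H_N = H_N, Tw_s = Tw_letters * t_w, nu = nu,
       n_trials_used = m)
}

#' Triple-extrapolation information rate
#'
#' Direct word-entropy estimate of the information rate: word entropies are
#' computed on a grid of data-size fractions, quantization levels `nu` and
#' word lengths `Tw`, then extrapolated by ordinary least-squares lines in
#' three successive limits - data size to infinity (linear in 1/size),
#' `nu` to infinity (linear in 1/nu), and word length to infinity (entropy
#' rate `H/Tw` linear in `1/Tw`). Returns `R = R_S - R_N`.
#'
#' @param ensemble a `response_ensemble` (canonically ~30 trials x 2000
#'   points with the first transient responses already removed).
#' @param size_fracs data-size fractions (default 5/10 ... 10/10).
#' @param nu_range quantization levels (default 4 ... 20).
#' @param Tw_range word lengths in letters (default 2 ... 7, the
#'   `1/Tw -> 0` extrapolation axis).
#' @return An `info_rate`: list with `R`, `R_S`, `R_N` (bits/s), `method`,
#'   and a `warning` field when entropy was non-monotone in data size
#'   (insufficient data).
#' @export
triple_extrapolation_rate <- function(ensemble,
                                      size_fracs = (5:10) / 10,
                                      nu_range = 4:20,
                                      Tw_range = 2:7) {
  dt <- ensemble$dt
  nonmono <- FALSE
  # H_inf[nu, Tw, c(S, N)]: entropies extrapolated to infinite data
  HS_inf <- HN_inf <- matrix(NA_real_, length(nu_range), length(Tw_range))
  for (ni in seq_along(nu_range)) {
    nu <- nu_range[ni]
    q <- quantize_ensemble(ensemble$y, nu)
    for (ti in seq_along(Tw_range)) {
      L <- Tw_range[ti]
      e_full <- encode_words(q, L, nu)
      hs <- hn <- numeric(length(size_fracs))
      for (si in seq_along(size_fracs)) {
        m <- max(2L, round(size_fracs[si] * nrow(e_full)))
        e <- e_full[seq_len(m), , drop = FALSE]
        hs[si] <- entropy_bits(as.vector(e))
        hn[si] <- mean(apply(e, 2, entropy_bits))
      }
      if (is.unsorted(hs, strictly = FALSE) && is.unsorted(rev(hs))) {
        nonmono <- TRUE
      }
      x <- 1 / size_fracs
      HS_inf[ni, ti] <- unname(coef(lm(hs ~ x))[1])
      HN_inf[ni, ti] <- unname(coef(lm(hn ~ x))[1])
    }
  }
  # nu -> infinity: linear in 1/nu
  xnu <- 1 / nu_range
  HS_nu <- apply(HS_inf, 2, function(h) unname(coef(lm(h ~ xnu))[1]))
  HN_nu <- apply(HN_inf, 2, function(h) unname(coef(lm(h ~ xnu))[1]))
  # Tw -> infinity: entropy rate H/Tw linear in 1/Tw
  Tw_s <- Tw_range * dt
  xT <- 1 / Tw_s
  R_S <- unname(coef(lm(I(HS_nu / Tw_s) ~ xT))[1])
  R_N <- unname(coef(lm(I(HN_nu / Tw_s) ~ xT))[1])
  out <- structure(list(R = R_S - R_N, R_S = R_S, R_N = R_N,
                        method = "triple_extrapolation",
                        warning = if (nonmono)
                          "entropy non-monotone in data size" else NULL),
                   class = "info_rate")
  if (nonmono) warning("entropy non-monotone in data size; ",
                       "extrapolation may be unreliable")
  out
}

#' Information rate of a Poisson photon stream
#'
#' Treats the per-bin photon-count ensemble exactly like a response
#' ensemble (signal/noise split, SNR spectrum, Shannon integral), yielding
#' the input information rate used in encoding-efficiency estimates.
#'
#' @param stream a `photon_stream` with >= 2 trials.
#' @param ... passed to [shannon_rate()].
#' @return An `info_rate`.
#' @export
input_information_rate <- function(stream, ...) {
  ens <- response_ensemble(stream$counts, stream$dt,
                           provenance = list(mean_rate = stream$mean_rate))
  r <- shannon_rate(snr_spectrum(ens), ...)
  r$method <- "shannon_input"
  r
}

#' Encoding efficiency
#'
#' `eta = R_output / R_input`. By the data-processing inequality a single
#' sampling chain cannot exceed `eta = 1`.
#'
#' @param R_output output information rate (bits/s), or an `info_rate`.
#' @param R_input input information rate (bits/s, > 0), or an `info_rate`.
#' @return List with `eta`, `R_output`, `R_input`.
#' @export
encoding_efficiency <- function(R_output, R_input) {
  ro <- if (inherits(R_output, "info_rate")) R_output$R else R_output
  ri <- if (inherits(R_input, "info_rate")) R_input$R else R_input
  if (ri <= 0) stop("R_input must be positive")
  list(eta = ro / ri, R_output = ro, R_input = ri)
}

#' @export
print.info_rate <- function(x, ...) {
  cat(sprintf("<info_rate> %.1f bits/s (%s)%s\n", x$R, x$method,
              if (!is.null(x$R_sd)) sprintf(" +/- %.1f SD", x$R_sd) else ""))
  invisible(x)
}
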