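# shared fixtures, generated in code

# small response ensemble with a known sinusoidal signal plus iid noise
sine_ensemble <- function(n_trials = 20, n = 2000, f = 50, A = 1,
                          sigma = 0.5, dt = 0.001, seed = 42) {
  set.seed(seed)
  tt <- (seq_len(n) - 1) * dt
  sig <- A * sin(2 * pi * f * tt)
  y <- matrix(rep(sig, each = n_trials), n_trials) +
    matrix(rnorm(n_trials * n, sd = sigma), n_trials)
  response_ensemble(y, dt)
}

# two-state symmetric Markov chain with switch probability p per letter
markov_trace <- function(n = 2000, p = 0.1, seed = 5) {
  set.seed(seed)
  x <- numeric(n)
  for (i in 2:n) x[i] <- if (runif(1) < p) 1 - x[i - 1] else x[i - 1]
  x
}

# hand-made flat spectral estimate over the 0..500 Hz grid (df = 2 Hz)
flat_spectrum <- function(snr) {
  structure(list(frequencies = seq(0, 500, by = 2),
                 signal_power = rep(snr, 251), noise_power = rep(1, 251),
                 snr = rep(snr, 251),
                 n_signal_segments = 7L, n_noise_segments = 60L,
                 degenerate_noise = FALSE),
            class = "spectral_estimate")
}
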