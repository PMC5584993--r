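# rhabdom

Stochastic modelling and information-theoretic analysis of insect
photoreceptor vision: how *Drosophila* R1-R6 cells, sampling light with
~30,000 refractory microvilli and moving their receptive fields by
photomechanical "microsaccades", encode bursty saccadic stimuli at maximal
information rates and resolve moving objects finer than the compound eye's
optical limit.

The package is for computational and sensory neuroscientists who want a
reusable, tested implementation of this modelling pipeline: stimulus
synthesis, the refractory photon-sampling photoreceptor model, Shannon and
direct (word-entropy) information estimators, and the dynamic
receptive-field acuity layer.

## The models in brief

**Refractory photon sampling.** Light arrives as an inhomogeneous Poisson
photon stream (absorbed rate `lambda(t)` proportional to intensity). Each
photon lands uniformly on one of `N = 30,000` microvilli; a free
microvillus produces one quantum bump after a stochastic latency and is
then refractory for 50-300 ms, so the transduced rate saturates as
`r = lambda / (1 + lambda E / N)` with `E` the mean busy time. Bumps of
fixed amplitude and gamma waveform `h(t)` sum linearly and pass a linear
membrane stage. Output noise is bump shot noise (Campbell's theorem);
dark intervals rescue refractory microvilli, which is why high-contrast
bursts are encoded so well.

**Information.** For a repeated-stimulus ensemble the signal is the trial
mean and the noise each trial's residual. `SNR(f)` comes from
Blackman-Harris-windowed periodograms (60 noise / 7 signal segments for a
20 x 2000 ensemble) and

```
R = integral over 2..500 Hz of log2(1 + SNR(f)) df   (bits/s),
```

with an independent triple-extrapolation word-entropy estimator
(`R = R_S - R_N`, extrapolated in data size, quantization levels and word
length) as a cross-check, and encoding efficiency
`eta = R_output / R_input` against the Poisson input information.

**Microsaccadic acuity.** A Gaussian receptive field (acceptance angle
`delta_rho`, FWHM) views two 1.7-degree dots crossing at constant speed.
Light input drives a photomechanical contraction (thresholded logarithmic
sensitivity, ~20 ms latency, fast attack, slower return, subtractive
adaptation) that shifts the field front-to-back by up to 4 degrees,
narrows it from 8.1 to 4.0 degrees and sheds captured light; the displaced
field samples the scene on the next 1-ms step. Two-point resolvability is
the Rayleigh percent dip `D = 100 (min(P1,P2) - T) / min(P1,P2)` of the
mean response. The closed loop turns fused single humps into separated
transients over a broad speed band - hyperacute vision below the
4.5-degree interommatidial angle.

## Worked example

```r
library(rhabdom)

# 100 Hz high-contrast burst stimulus in darkness (BG0), 2 s at 1 kHz
stim <- burst_stimulus(cutoff_hz = 100, BG = 0, seed = 1)
stim$contrast
#> [1] 1.420818        # ~ sqrt(pi - 1) = 1.4633, the clipped-Gaussian limit

# simulate 20 trials of the 30,000-microvillus model at 8e5 photons/s
ens <- simulate_ensemble(stim, mean_rate = 8e5, n_trials = 20, seed = 2)
shannon_rate_chunked(ens)
#> <info_rate> 617.4 bits/s (shannon_chunked) +/- 27.9 SD

# hyperacuity: two 1-degree-apart dots crossing at 10 deg/s
sim <- simulate_acuity(moving_dot_scene(separation = 1, speed = 10),
                       gaussian_rf(8.1), microsaccade_kinetics(),
                       n_trials = 8, seed = 6)
sim$resolvability
#> <resolvability> D = 36.5% (resolved)
```

The contrast is the RMS contrast (SD/mean) of the clipped burst; the
chunked Shannon rate (mean +/- SD over eleven 1000-point chunks) sits near
the published ~633 bits/s infomax of the full stochastic photoreceptor
model; and the microsaccadic model resolves dots well below both the
acceptance angle and the ommatidial spacing when they move at a suitable
speed.

Experiment runners reproduce whole analyses as tables:
`run_encoding_gamut()` (bandwidth x background information grid),
`run_walk_analysis()` (saccadic vs linear vs shuffled viewing of 1/f
panoramas), `run_dots_acuity()` (classic vs microsaccadic model on the
6.8-degree dot pair) and `run_heatmap()` (separation x speed
resolvability map).

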