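---
title: "Refractory photon sampling and microsaccadic vision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refractory photon sampling and microsaccadic vision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rhabdom` models how a fly photoreceptor (an R1-R6 cell of the *Drosophila*
compound eye) encodes light in time and resolves moving objects over space.
Its two core ingredients are (i) stochastic photon sampling by a population
of refractory microvilli and (ii) a dynamic, photomechanically driven
receptive field ("microsaccadic sampling"). Around these sit a stimulus
generator, information-theoretic estimators, and experiment runners. This
vignette explains the models, their assumptions, the defaults and why they
were chosen, and what the synthetic data can and cannot show.

## Refractory photon sampling

A photoreceptor's rhabdomere is treated as `n_microvilli = 30000`
independent sampling units. Per trial, photons arrive as an inhomogeneous
Poisson stream whose per-bin rate is proportional to the light stimulus and
scaled to a stated mean absorbed rate (photons/s). Each photon lands on one
microvillus, chosen uniformly at random. A photon landing on a free
microvillus elicits exactly one quantum bump after a stochastic latency;
the unit is then refractory, and photons arriving during the latency or the
refractory period are lost. Bumps have a fixed amplitude and a normalized
gamma waveform `h(t) ~ (t/tau)^(n-1) exp(-t/tau)` (order 3, time-to-peak
4 ms), and the summed bump train passes one linear first-order membrane
stage (`tau_m` = 2 ms, a bright-adapted value).

Assumptions worth making explicit:

* **Non-paralyzable dead time.** A photon arriving during refractoriness is
  lost without extending the refractory period. For a constant
  per-microvillus rate `lambda` the transduced rate is the renewal-theory
  value `lambda / (1 + lambda * E)`, with `E` the mean busy time
  (latency + refractory period); the test suite checks this oracle at
  single-microvillus and whole-cell scale, and recovers the mean refractory
  period within 10% by fitting the same law to simulated saturation curves.
* **Linear summation.** Bumps add; output noise therefore obeys Campbell's
  theorem (variance `r a^2 sum(h^2) dt`, power spectrum shaped by
  `|h(f)|^2`), also under test.
* **Fixed bump amplitude and a linear membrane.** The full published
  photoreceptor model light-adapts its bump amplitude and waveform and has
  a nonlinear membrane; both are deliberately omitted here. Information
  estimates are invariant to any common linear filter, so the membrane
  stage carries no information-theoretic weight. The important consequence
  is discussed under *Known limitations*.

### Calibrated stochastic laws

The refractory period is constrained to 50-300 ms and the latency is only
loosely constrained, so the package fixes one concrete choice and keeps it
for every analysis:

| parameter | default | notes |
|---|---|---|
| refractory period | log-normal, `meanlog -1.3436`, `sdlog 0.35`, truncated to [50, 300] ms | truncated mean 220 ms |
| bump latency | gamma, mean 12 ms, CV 0.6 | blocks the microvillus while pending |
| bump waveform | gamma order 3, time-to-peak 4 ms, amplitude 1 | bright-adapted, near-minimal bumps |
| membrane | first-order, `tau_m` 2 ms, gain 1 | linear, information-invariant |

These two distributions were calibrated once, jointly, so that the
benchmark operating point - a 2-s, 100-Hz-bandwidth high-contrast burst
stimulus in darkness (BG0) at 8e5 absorbed photons/s, 20 trials - yields a
chunked Shannon information rate close to 633 bits/s, the published
infomax of the full stochastic photoreceptor model, while the information
maximum across stimulus bandwidths stays at the 100 Hz cutoff. All
simulations and the acceptance script then use these frozen defaults.

## Stimuli

`make_bandlimited_gwn()` draws Gaussian white noise, applies a
Fourier-domain brick-wall low-pass (20-500 Hz cutoffs), and rescales so
that the post-filter SD is `peak_to_peak / 6`; the 6-sigma convention
makes a nominal 2-unit peak-to-peak series have SD 1/3 at every cutoff,
which reproduces the printed stimulus contrasts (SD/mean of 0.22 on the
bright 1.5-unit background). `apply_background()` adds the pedestal and
clips at zero; clipping on dark backgrounds creates bursts with prolonged
dark intervals, and the resulting RMS contrast converges to the analytic
rectified-Gaussian value `sqrt(pi - 1) ~ 1.463` at BG0 regardless of the
modulation SD or bandwidth. The brick wall differs from the analog
elliptic filter used in the original experiments; only the flat pass-band
matters for the analyses here.

Natural scenes are emulated by `synth_panorama()`: circular 360-degree
line scans with `1/f` amplitude spectra and random phases (0.05 degrees
per pixel by default), floored at a small positive intensity. Gaze is
emulated by `synth_saccadic_walk()`: brief raised-cosine saccades
(~1-5 per second, peak 200-800 deg/s, flagged at the conventional
|velocity| >= 200 deg/s criterion) alternating with intersaccadic bouts
that mix quiet fixation jitter with slower drift/turning, as walking flies
do. The drift bouts matter: the published walking trace has a median
absolute yaw velocity of ~63 deg/s, far faster than fixational jitter
alone, and the linear-viewing control is defined as that median. Without
drift, the "linear" control would move slower than the fixations it is
contrasted with and the saccadic/linear comparison would invert. With the
defaults, saccadic viewing gives first-derivative histograms with higher
zero-bin peaks and heavier tails (higher kurtosis) than median-velocity
viewing in essentially every seed, which is the qualitative signature the
walk experiment checks. Exact histogram counts are image- and
binning-specific and are not reproduction targets.

## Information estimates

The signal is the across-trial mean; each trial's noise is its deviation.
Spectra use 500-point Blackman-Harris 4-term windows (the standard
coefficient set) with the window-power correction. Signal traces are
segmented with 50% overlap (seven segments per 2000-point trace); noise
traces with stride 750 (three per trace), so the canonical 20 x 2000
ensemble yields 60 noise and 7 signal spectral segments, matching the
published bookkeeping (whose prose is internally inconsistent; the printed
counts are taken as normative). `shannon_rate()` integrates
`log2(1 + SNR(f))` over 2-500 Hz by trapezoid; flat-SNR closed forms
(SNR 1 -> 498 bits/s, SNR 3 -> 996 bits/s) pin the implementation down.
Reported rates use eleven 1000-point chunks with 100-point shifts
(mean +/- SD). Where noise power underflows (synthetic noiseless
ensembles) the SNR is capped at 1e7 with a warning.

The direct (triple-extrapolation) estimator digitizes responses into `nu`
equal-width levels (ties at bin edges go to the lower bin), forms words of
2-7 one-millisecond letters at sliding positions, and extrapolates
ordinary least-squares lines in `1/size` (fraction of trials), `1/nu`,
and `1/T_w`, returning `R = R_S - R_N`. Sliding words use every letter of
the limited data at each word length; with non-overlapping words the
estimator is noticeably more biased on 2000-point records. The noise
entropy averages over all complete word positions (how partial words at
the record edges should be treated is unstated in the source method; they
are simply dropped). On a two-state Markov chain with a known entropy
rate the estimator lands within a few percent; on simulated 20-Hz burst
ensembles (30 x 2000) it differs from the Shannon estimate by roughly
5-20%, consistent with the published comparison of the two methods.

Encoding efficiency is `eta = R_output / R_input`, with `R_input`
estimated by treating repeated Poisson photon-count streams exactly like a
response ensemble. Because the model is a pure sampling chain, the
data-processing inequality requires `eta < 1` for every stimulus
condition; the property suite checks all 20 cells of the bandwidth x
background grid.

## The photon-rate optimization and a deliberate divergence

`optimize_photon_rate()` simulates the model across a photon-rate grid
and returns the information argmax, mimicking the photomechanical
adaptations (pupil and rhabdomere contractions) that regulate how much
light the rhabdomere absorbs. In the full published model, information
peaks at an interior rate (8e5 photons/s at BG0) and declines with further
brightening. In this package's model class - fixed-amplitude bumps,
non-paralyzable refractoriness, linear membrane - output information is a
*saturating but monotone* function of the absorbed rate: more photons
always make the bump train more reproducible, just with diminishing
returns. The interior optimum of the full model comes from the adaptation
mechanisms this package deliberately omits. Consequently:

* the encoding-gamut runner bounds its optimization grid by the published
  physiological range of effective absorbed rates (1e4 to 8e5 photons/s),
  treating the photomechanical ceiling as a constraint rather than an
  emergent property; within that grid the information maximum falls at the
  100 Hz cutoff at BG0, as published;
* an unconstrained grid search (as in the wide-grid sweep of the
  acceptance script) honestly reports the top of the grid, not 8e5 - this
  is a known, documented divergence of the reduced model, not a defect of
  the search.

## Microsaccadic receptive-field dynamics

The spatial layer describes one photoreceptor's angular sensitivity as a
Gaussian receptive field with acceptance angle (FWHM) `delta_rho` and unit
integral. Two bright dots (1.7-degree top-hats) cross the field at constant
speed; the classic prediction (`volterra_predict()`) convolves the static
light input with a causal temporal kernel and fuses nearby dots - the
motion-blur limit. Resolvability `D` is the percent dip between the two
largest local maxima, `100 (min(P1, P2) - T) / min(P1, P2)`, matching the
analytic two-Gaussian dip formula to under 1% absolute.

The microsaccadic model closes a feedback loop at 1-ms steps: the current
light input drives a contraction, and the displaced, narrowed receptive
field samples the scene at the next step. The kinetic chain is:

1. **Amplitude law.** Drive `u = log10(I / i_half) / log10(i_sat / i_half)`,
   zero below the threshold `i_half` (0.04 relative light-input units) and
   1 at `i_sat` (0.10). A pure logarithm makes ten-fold intensity steps
   produce equal displacement increments, the measured light-sensitivity
   signature. Brighter input overdrives the stage; only the displacement
   itself is clamped (at `max_displacement_um`), so brief bright inputs
   still commit full-scale contractions, as observed for 10-ms flashes.
2. **Drive adaptation.** A slow subtractive stage (`tau_adapt` 300 ms,
   full steady-state adaptation) acts on the drive, so gradual intensity
   ramps produce little net drive. This is what fuses dots crossing at
   2.5 deg/s or slower: the approach is adiabatic and the contraction
   never engages.
3. **Committed contraction.** The activation stage has a fast attack
   (`tau_rise` 25 ms) and a slow release (`tau_return` 100 ms): a brief
   photon surge commits a contraction that outlives it and returns more
   slowly, as the imaged rhabdomere movements do. With the 20-ms latency,
   a saturating flash starts moving 20 ms after onset and is maximally
   displaced 86 ms after onset, inside the measured 8-20 ms and
   70-200 ms windows. The latency sits at the top of its measured range
   because it doubles as the boundary-setter of the fast-speed regime:
   dots crossing at 200 deg/s and above outrun the delayed contraction
   and fuse, as the published map predicts.
4. **Optics.** Displacement (up to 1.2 um) converts to receptive-field
   shift at 3.33 deg/um (inferred from the printed 0.2-1.2 um vs
   0.5-4.0 deg pairing), in the front-to-back direction (the ommatidium
   lens inverts the rhabdomere's back-to-front motion). The acceptance
   angle narrows linearly with normalized displacement from 8.1 to
   4.0 degrees, and the *captured light shrinks in proportion to the
   acceptance angle* (peak angular sensitivity held): contraction moves
   the rhabdomere away from the focal point and sheds light, making the
   input transient.

This loop converts the fused single hump of the classic model into
separated intensity transients: the field flees ahead of the advancing
dots faster than they move, sheds light, then returns as adaptation
releases the contraction, producing object-locked response peaks. At high
speeds (>= 200 deg/s) the dots outrun the contraction and only wide
separations survive; at very slow speeds adaptation removes the drive and
the dots fuse. The same asymmetric front-to-back field motion makes
back-to-front crossings enter and leave the field earlier, giving the
phasic direction selectivity checked as a 2-10 ms half-maximum lead.

The simplest kinetic description of the contraction would be a linear
rise/decay kernel (a difference of exponentials) driven by the
instantaneous light input. Four refinements beyond that were needed to
reproduce the published behavior, and all are deliberate design choices:
the adapt-then-commit ordering (2), the asymmetric attack/release (3),
light shedding in proportion to narrowing (4), and the unclamped log
drive (1). Each has a direct experimental correlate noted above.

### Resolvability detection and its noise floor

`simulate_acuity()` scores the across-trial mean response, smoothed with a
5-ms moving average (scaled up for multi-second traverses), counting only
local maxima above 20% of the trace maximum. On top of the 1% default
floor, the effective noise floor is data-driven: photon noise that
survives trial averaging carves percent-scale dips into genuinely fused
responses, so a dip only counts as resolution if it exceeds an
extreme-value-scaled multiple of the standard error of the smoothed mean.
Without this, every cell of the resolvability map would read "resolved"
at the 1% floor under realistic trial counts.

## Problem sizes

Default analyses use 2-s, 1-kHz stimuli; 20 trials for spectral
information estimates, 30 for the triple-extrapolation comparison; 6-10
trials per photon-rate grid point; and 8 trials per resolvability-map
cell. These sizes keep every estimate within the sampling tolerances the
tests assert while remaining comfortable on a single CPU.

## Known limitations

* No bump amplitude/waveform adaptation, no intracellular pupil, no
  nonlinear membrane: hence the monotone rate-information curve discussed
  above, and fixed-size bumps at every background.
* The calibrated latency dispersion (CV 0.6) reproduces the published
  information rate but over-disperses bump timing relative to a real
  bright-adapted cell. The visible cost: 6.8-degree dots crossing at
  409 deg/s fuse in the simulated *response* (their light input is still
  two-peaked), whereas recordings resolve them; at 205 deg/s the model
  resolves them as observed. Similarly the model's resolvable band for
  3-degree dots starts at ~10 deg/s (published band ~5 deg/s), and
  4-degree dots at 200-300 deg/s fuse where the published map predicts
  resolution.
* One spatial dimension (azimuth); no elevation, no neural superposition
  across the six photoreceptors sharing an optical axis, no synaptic
  network information - simulated rates sit below the best recorded cells
  by design.
* Synthetic panoramas emulate only second-order (1/f) statistics of
  natural scenes; real scenes have phase structure (edges, objects) that
  the walk analyses do not capture. Passing tests show the pipeline's
  statistical machinery behaves correctly, not that the exact published
  histogram counts (image-specific) are reproduced.
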