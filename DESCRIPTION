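Package: rhabdom
Title: Refractory Photon Sampling and Microsaccadic Vision in Fly Photoreceptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and information-theoretic analysis of insect
    photoreceptor encoding. Generates band-limited Gaussian and bursty light
    stimuli, synthetic natural panoramas and saccadic gaze trajectories;
    simulates stochastic photon sampling by a population of refractory
    microvilli producing quantum bumps; estimates signal-to-noise spectra,
    Shannon and triple-extrapolation information rates and encoding
    efficiency; and models dynamic (microsaccadic) receptive fields to map
    two-point Rayleigh resolvability of moving objects across speeds and
    separations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
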