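Package: prestim
Title: State-Dependent Analysis of Prestimulus Oscillations, Hemodynamics,
    and Visual Contrast Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for state-dependent
    neuromodulation studies of visual perception. Generates synthetic
    experiments (adaptive-staircase visual detection under sham and
    transcranial random noise stimulation, occipital EEG band-power
    features, resting oxyhemoglobin series, fatigue ratings), extracts
    prestimulus Welch band power and HbO amplitude, fits hierarchical
    Bayesian mixed models with a highest-posterior-density decision rule
    via a Gibbs sampler, and performs a gradient-based sensitivity
    analysis of a regression network with eigen-decomposition feature
    attribution and label-permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
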