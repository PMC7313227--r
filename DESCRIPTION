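Package: spikedyn
Title: Spike-Initiation Dynamics and Neuronal Transfer-Function Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterization of neuronal spike-initiation dynamics from
    noisy current-clamp stimulation. Generates and calibrates
    Ornstein-Uhlenbeck current stimuli, simulates reduced leaky and
    exponential integrate-and-fire neurons, estimates the first-order
    dynamical transfer function by spike-triggered averaging (with a
    bootstrap surrogate significance threshold), extracts the encoding
    cut-off frequency and the high-frequency power-law exponent, quantifies
    passive membrane properties and action-potential waveforms (threshold,
    onset rapidness, dynamic I-V slope factor), classifies electrical
    phenotypes from inter-spike-interval patterns, and runs population-level
    correlation and group-comparison analyses on synthetic cell cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
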