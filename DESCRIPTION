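Package: hubsim
Title: Cortical Microcircuit Simulation with Assemblies of Weight-Hub Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation and analysis of single cortical layers
    built from stochastic generalized integrate-and-fire (GIF) neurons with
    spike-triggered adaptation currents and a dynamic firing threshold.
    Constructs excitatory networks whose synaptic weights follow lognormal
    distributions with inward weight correlations, labels weight-hub neurons,
    and rewires them into densely connected assemblies while preserving the
    overall connection probability and weight distribution. Provides
    spontaneous-activity, step-current stimulation and Poisson-barrage
    protocols; up/down-state segmentation with duration and transition-time
    correlation statistics; empirical gain-function estimation with
    mean-field fixed-point classification; and a two-stage K-means procedure
    for recovering hub neurons and their assemblies from simulated activity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
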