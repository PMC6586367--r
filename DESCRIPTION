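Package: ratechaos
Title: Dynamical Mean-Field Theory for Random Networks of Multi-Dimensional Rate Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze large randomly connected networks of rate neurons
    whose single-unit dynamics are multi-dimensional, with spike-frequency
    adaptation as the leading example. Provides fixed-point stability analysis
    (critical coupling, Hopf/saddle-node regime classification, resonance
    frequency, Jacobian spectra), a self-consistent dynamical mean-field solver
    for the power spectrum of the chaotic phase with and without oscillatory
    drive and parameter heterogeneity, maps of Gaussian second-order statistics
    through static nonlinearities by four interchangeable methods, a microscopic
    network simulator serving as the empirical oracle, and scalar metrics
    (Q-factor, correlation time, signal-to-noise decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
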