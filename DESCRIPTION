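Package: predalign
Title: Predictive Alignment Learning for Chaotic Recurrent Networks
Version: 0.1.0
Authors@R:
    person("predalign", "maintainers", email = "predalign@example.org",
           role = c("aut", "cre"))
Description: Simulator and training library for recurrent neural networks
    that are initially chaotic. Implements the predictive-alignment
    plasticity rule, in which plastic recurrent weights learn to predict
    random output feedback while aligning with the chaotic recurrent
    drive, together with a least-mean-square readout, a FORCE (recursive
    least squares) baseline, leaky integrate-and-fire network variants,
    generators for the full task battery (periodic signals, Lorenz
    attractor, Ready-Set-Go timing, memory bits, synthetic movies), and
    dynamical diagnostics (leading Lyapunov exponent, representational
    efficiency, eigenvalue spectra, tent maps, fixed-point probes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
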