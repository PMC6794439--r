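Package: astromod
Title: Digital Emulation of Astrocytic Calcium Oscillation Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the coupled integrate-and-fire neuron / De Pitta
    astrocyte calcium model (2-AG release, IP3 production, IP3R-gated
    calcium-induced calcium release) and emulates a multiplierless digital
    realization of the same dynamics: piecewise-linear approximations of the
    nonlinear gating functions, shift-add (single constant multiplication)
    plans for every constant multiply, and signed Q4.34 fixed-point forward
    Euler stepping with saturation. Includes oscillation analysis
    (peak statistics, steady/oscillatory/damped regime calls, AM/FM/AFM
    modulation classification), phase-plane export, and RMSE/NRMSE
    reference-versus-digital comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
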