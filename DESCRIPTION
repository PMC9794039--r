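Package: qsignal
Title: Queueing-Network Simulation of Insulin Signalling and GLUT4
    Translocation in Adipocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time stochastic simulation of the insulin/PI3K/Akt/mTOR
    signalling pathway in adipocytes, modelling molecular species as integer
    queues whose Michaelis-Menten or mass-action reaction rates are converted
    to per-step transfer probabilities. Includes the GLUT4 vesicle/membrane
    translocation cycle, a glycolysis fragment with GAPDH-occupancy-gated
    Rheb/mTORC1 activation and the mTORC1/S6K negative feedback on IRS1/3,
    noisy multi-cell ensembles, a genetic-algorithm calibrator for reaction
    scaling coefficients, sweep experiments over GAPDH availability and mTORC1
    inhibition, and a deterministic ODE reference integrator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
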