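Package: togglectl
Title: Modelling and In Silico Control of a Bistable Genetic Toggle Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of the LacI/TetR genetic
    toggle switch with inducer (aTc/IPTG) exchange, phase-portrait analysis
    (nullclines, equilibria, separatrix, time-averaged vector fields under
    periodic forcing), closed-loop proportional-integral and bang-bang control
    of a virtual cell, and model calibration by covariance matrix adaptation
    evolution strategy with parameter-recovery diagnostics on synthetic
    single-cell fluorescence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
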