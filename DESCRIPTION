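Package: bifinfer
Title: Parameter Inferability Around Co-Dimension 1 Bifurcations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how co-dimension 1 bifurcations (saddle-node,
    transcritical, supercritical and subcritical pitchfork) shape the
    inferability of kinetic parameters and initial conditions in
    one-dimensional ordinary differential equation models. Provides the four
    normal forms with analytic fixed-point structure and closed-form
    solutions, a fixed-step fourth-order Runge-Kutta integrator with
    finite-time blow-up detection, seeded synthetic observations with
    Gaussian measurement noise, log-likelihood surfaces and
    maximum-likelihood estimation over the (bifurcation parameter, initial
    condition) plane, and observed Fisher information maps computed from
    finite-difference Hessians of the log-likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
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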