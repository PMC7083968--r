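Package: combobench
Title: Evaluation of Drug-Combination Response Surfaces and Synergy Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing two-drug combination (checkerboard) assays.
    Implements single-agent Hill dose-response fitting (median-effect
    linearisation and nonlinear least squares), non-interacting reference
    surfaces (Loewe/URSA additivity with an asymptotic extension to unequal
    maximal effects, and Bliss independence), the BRAID parametric response
    surface with its interaction parameter kappa and the index of achievable
    efficacy (IAE), and the classical interaction metrics (Bliss volume,
    Chou-Talalay and least-squares Combination Index).  Includes a
    checkerboard simulator with Gaussian response noise and log-normal
    dosing error, Monte-Carlo pipelines that quantify the slope- and
    efficacy-dependent biases of index-based synergy calls, a synthetic
    multi-drug multi-cell-line screen generator with planted mechanism
    classes, and screen-level analytics: interaction-profile clustering
    scored by the adjusted Rand index, relative-sensitivity scoring,
    phenotype projection, and expression-association ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
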