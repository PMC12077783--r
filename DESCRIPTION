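Package: cohesim
Title: Agent-Based Simulation of Cohesion-Gradient-Driven Collective Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-dimensional agent-based simulator of small cell clusters in
    which an internal gradient of intercellular cohesion, combined with
    stochastic protrusions of the outermost cells, produces persistent
    directed migration of the cluster centre of mass. Cells are coupled by
    viscoelastic bonds (Kelvin-Voigt or Standard Linear Solid) integrated
    with classical Runge-Kutta under strong environmental damping. The
    package includes closed-form predictions for truncated half-Gaussian
    protrusion statistics and the resulting cluster drift speed, trajectory
    analysis tools (centre-of-mass speed estimation, ensemble mean-squared
    displacement with through-origin linear and quadratic fits, chemotactic
    index), and scripted parameter-sweep experiments with seeded replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
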