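Package: tendontwist
Title: Finite-Element Analysis of Fascicle Twist in the Achilles Tendon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A transversely isotropic hyperelastic finite-element pipeline for
    studying the mechanical role of fascicle twist in the human Achilles
    tendon. Builds hexahedral tendon meshes from elliptical cross-section
    profiles, embeds helical fiber twist as a fitted Euler-angle nodal field,
    solves static large-deformation equilibrium with a Newton-Raphson solver
    (including frictionless sliding interfaces between sub-tendons), performs
    inverse material-parameter calibration against marker-tracking stretch
    experiments, and runs in-silico rupture, sub-tendon sliding, and
    sensitivity studies under differential triceps-surae loading. A
    synthetic-data generator emulates cadaver geometry and cyclic-stretch
    experiments so the whole pipeline is reproducible from seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
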