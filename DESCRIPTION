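Package: glidebuckle
Title: Self-Buckling Analysis of Gliding Filamentous Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify propulsion forces and friction coefficients of
    gliding filamentous cyanobacteria from their self-buckling behaviour.
    Implements the linear stability theory of the self-propelled elastica
    (critical activity coefficient and critical length), nonlinear Kirchhoff
    shape dynamics by the method of lines, fitting of theoretical buckling
    profiles to observed contour tracks, weighted logistic regression of
    collision outcomes (length-only and velocity-coupled), three-point
    micropipette bending analysis, an overdamped Langevin bead-chain
    simulator of filament-obstacle collisions, and synthetic-data generators
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    deSolve,
    jsonlite,
    readr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
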