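Package: bubblerelax
Title: Relaxation Dynamics of Denaturation Bubbles in Coarse-Grained DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Microcanonical molecular dynamics of the Peyrard-Bishop-Dauxois
    (PBD) lattice model of homopolymer DNA, with tools to insert Gaussian
    denaturation bubbles into thermalised chains at fixed total energy,
    compute ensemble-averaged displacement and energy autocorrelation
    functions over the bubble region, and extract characteristic relaxation
    times through stretched-exponential (Kohlrausch-Williams-Watts) fits
    with bootstrap uncertainties and amplitude/width trend analyses.
    Includes a symplectic Runge-Kutta-Nystrom integrator with an explicit
    energy-drift contract, synthetic-fixture generators with known ground
    truth, and a reproducible experiment orchestration layer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
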