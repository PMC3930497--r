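Package: rbdna
Title: Rigid-Body Dynamics Simulation of DNA Under Magnetic Tweezers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico magnetic-tweezers rig for coarse-grained DNA. A DNA
    molecule is modelled as a chain of rigid cylinders (capsules) connected by
    ball-and-socket joints, with bending and twisting elasticity calibrated
    from persistence lengths through a Langevin-function relation, excluded
    volume via capsule collision handling, and local or global (stochastic
    velocity rescaling) Langevin thermostats. Constraints are solved at the
    velocity level (error-reduction and constraint-force-mixing softening)
    with an exact O(N) block-tridiagonal solver for collision-free chains,
    projected successive over-relaxation for contacts and a direct active-set
    fallback. Force-clamp, turn-clamp and torque-clamp protocols reproduce
    force-extension curves, rotation-extension ("hat") curves and
    torque-overtwist response, with observables for twist, writhe, linking
    number, kinetic-energy statistics, autocorrelation times, persistence
    length and plectoneme geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    readr,
    mclust
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse,
    jsonlite,
    withr,
    pracma,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
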