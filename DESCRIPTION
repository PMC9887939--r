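Package: rootpattern
Title: Water-Limited Vegetation Patterns Driven by Root-Augmentation Feedback
Version: 0.1.0
Authors@R: person("Rootpattern", "Developers", role = c("aut", "cre"),
    email = "rootpattern@example.org")
Description: Simulates and analyses a two-species (shrub-sedge) water-limited
    vegetation model with nonlocal water uptake by laterally extended roots.
    Root zones widen as shoots grow (root-augmentation feedback), generating a
    scale-dependent feedback that drives Turing-type spatial patterning, and
    new shrub clones sprout at a distance through a fat-tailed root-sucker
    kernel. The package provides a pseudo-spectral RK4 solver with FFT
    convolutions, a fixed-width kernel approximation for the biomass-dependent
    root kernel, linear stability and dispersion-relation analysis of the
    uniform states, bifurcation scans over precipitation, and a patchy-invasion
    pipeline that classifies complete versus incomplete invasion and locates
    the precipitation threshold separating them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
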