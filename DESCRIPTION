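Package: landgenr
Title: Individual-Based Landscape Genetics over Resistance Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for individual-based landscape genetics of
    spatially structured wildlife populations: reading diploid microsatellite
    genotypes (Genepop and CSV dialects), Rousset's a_r genetic distance and
    Weir-Cockerham pairwise F_ST, maximum-likelihood pairwise relatedness
    with allele-randomization significance, geographic, least-cost-path and
    barrier-crossing distances over resistance rasters, simple and partial
    Mantel tests with reciprocal causal modelling, distance-based linear
    models (pseudo-F with permutation), and a Bayesian MCMC estimator of
    recent directional migration rates among local populations. A forward-time
    synthetic-data generator emulates the sampling design of a partially
    migratory caribou metapopulation so every stage can be validated without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
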