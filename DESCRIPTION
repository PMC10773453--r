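Package: phycomp
Title: Phylogenetic Comparative Methods: Discrete and Continuous Trait
    Evolution, Stochastic Character Mapping, and Diversification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogenetic comparative analysis: extended Mk
    models of discrete character evolution with design-matrix model
    specification, maximum-likelihood fitting, AIC model comparison, and
    marginal/joint ancestral state reconstruction; state-space expansions
    for intraspecific polymorphism and hidden rate categories; stochastic
    character mapping with Akaike-weight model averaging and posterior
    summaries; continuous-trait methods including phylogenetic signal
    (Blomberg's K and Pagel's lambda), maximum-likelihood and Bayesian
    MCMC ancestral states, multi-regime multivariate Brownian motion,
    penalized-likelihood variable-rate Brownian motion, and phylogenetic
    principal components; and diversification analyses (lineage-through-
    time curves, the gamma statistic, the MCCR test, and Yule/birth-death
    model fitting with incomplete sampling fractions). Includes a
    reproducible synthetic fixture generator for trees and traits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
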