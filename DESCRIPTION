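Package: eyescale
Title: Phylogenetic Allometry, Evolutionary Rates, and Habitat Analysis of
    Insect Eye Size
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the macroevolution of compound-eye size in
    butterflies and other insects. Implements phylogenetic generalized least
    squares under Brownian motion, Pagel's lambda and Ornstein-Uhlenbeck
    correlation structures; an individual-level phylogenetic linear mixed
    model for allometric regressions with sex and family effects; maximum
    likelihood fitting of homogeneous-rate trait-evolution models (Brownian
    motion, Ornstein-Uhlenbeck, early burst, trend, white noise) with AICc
    model weights and posterior-tree sensitivity analysis; a reversible-jump
    MCMC variable-rates regression with branch rate scalars, stepping-stone
    marginal likelihoods and Bayes factors; a penalized-likelihood multi-rate
    Brownian motion model; and habitat quantification from transect
    monitoring records against a tree-cover raster, including
    community-weighted mean trait analysis. A synthetic-data generator
    produces complete input bundles (tree, individual traits, posterior tree
    sets, monitoring records) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme
Config/testthat/edition: 3
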