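Package: shinglmcc
Title: Monosynaptic Connectivity Inference from Spike-Train Cross-Correlograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed monosynaptic connections between simultaneously
    recorded neurons from their spike-train cross-correlograms. Implements the
    Classical flat-null correlogram test, the penalized Poisson generalized
    linear model GLMCC with a smoothness prior on the background, and its
    cusp-tolerant revision ShinGLMCC, with Wilks likelihood-ratio detection and
    a grid search over synaptic timescale and transmission delay. Also provides
    doubly stochastic Poisson generators (oscillatory, Ornstein-Uhlenbeck,
    Markov-switching rates) with their closed-form correlograms, a
    multi-timescale adaptive-threshold (MAT) spiking-network simulator for
    ground-truth benchmarks, and macro-averaged Matthews-correlation scoring of
    estimated connection matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
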