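Package: watermaze
Title: Multi-Strategy Reinforcement-Learning Simulation of Water-Maze Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates rodent spatial navigation in the Morris water maze with a
    modular agent combining a model-free cue-guided Direction strategy (TD
    Q-learning over action cells), a model-based Planning strategy (activation
    diffusion over a topological graph of Hebbian-learned place cells), a
    model-free Locale strategy, and random Exploration with persistence, all
    arbitrated by a learned gating network with winner-take-all selection.
    Provides the six classical experimental protocols (reference memory, delayed
    matching to place, cue/place competition, gradual cue competition,
    generalization gradient, blocking), tidy analysis of escape latencies,
    region occupancy, strategy selection rates and responder classification,
    and exact nonparametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
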