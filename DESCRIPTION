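Package: netarch
Title: Network Archaeology: Inferring Node Arrival Order from a Single Graph Snapshot
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for recovering the temporal order in which nodes joined a
    grown network from one observed, randomly relabeled snapshot. Implements
    seeded simulators for preferential-attachment, uniform-attachment and
    Cooper-Frieze growth models; the Peeling algorithm that recovers the
    snapshot's age-oriented directed acyclic graph and bins nodes by removal
    round; partial-order estimators (perfect-precision, Peeling, Peeling+)
    scored by density, precision and recall; exact and Markov chain Monte
    Carlo estimation of posterior pair-order probabilities via linear
    extensions of the recovered DAG; a linear-programming upper bound on the
    optimal precision/density tradeoff; and construction of brain-region
    networks from correlation matrices with Peeling-based region ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
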