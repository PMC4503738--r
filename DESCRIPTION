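Package: tiesim
Title: Weighted Social Network Formation with Tie Aging and Deletion
Version: 0.1.0
Authors@R: person("tiesim", "maintainers", email = "tiesim@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulator of weighted social network formation by
    cyclic closure (weighted two-step local attachment) and focal closure
    (global attachment), with three interchangeable tie-termination
    mechanisms: node deletion, link deletion, and multiplicative link aging
    with a removal threshold. Includes the companion analysis suite (degree,
    strength and weight distributions with maximum-likelihood power-law
    exponents, neighbourhood overlap versus weight, clustering and
    nearest-neighbour degree profiles, in-repo Louvain modularity,
    intra-community weight homogeneity, weighted link communities with
    partition density, and link-percolation analysis of weak-tie bridging)
    together with the mean-field clique theory for the aging model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
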