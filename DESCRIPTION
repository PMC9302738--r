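Package: sparselv
Title: Assembly and Equilibria of Sparsely Interacting Competitive
    Lotka-Volterra Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates community assembly from a species pool under the
    symmetric competitive Lotka-Volterra equations on sparse interaction
    networks (random regular and Erdos-Renyi community graphs, optionally
    with Gaussian heterogeneity in interaction strength). Decomposes
    equilibria into connected subgraphs of persistent species, computes
    closed-form and numeric critical interaction strengths for allowed
    subgraphs (tree catalogue, feasibility/stability bisection), and
    locates the diversity jumps, the percolation transition of the
    largest persistent component, and the unique-to-multiple-equilibria
    transition, with finite-size-scaling estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
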