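Package: hdperc
Title: History-Dependent Percolation on Multiplex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generational (history-dependent) percolation on multiplex
    networks: an iterative cluster-refinement process in which each
    generation keeps a layer's links only when both endpoints already
    share a cluster, together with its two-layer mean-field theory
    (generation recursion, finite-generation thresholds, and the
    discontinuous infinite-generation fixed point), random-network
    generators (Erdos-Renyi, truncated power-law configuration model,
    top-weight thresholding of weighted matrices, and a synthetic
    correlated bilayer fixture), and Monte Carlo protocols for
    finite-size scaling, bimodal order-parameter classification and
    pseudo-critical-point detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
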