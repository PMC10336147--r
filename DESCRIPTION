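Package: nanoirr
Title: Neighborhood Irregularity Indices for Nanotube Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes eleven edge-additive irregularity indices of molecular
    graphs (Albertson-type descriptors and their logarithmic, ratio and
    square-root variants) under either the classical vertex-degree weighting
    or the neighborhood degree-sum weighting, working from a graph or
    directly from an edge partition. Includes programmatic generators for the
    HAC5C7[p,q] and HAC5C6C7[p,q] pentagon/heptagon nanotube lattice graphs,
    exact closed-form evaluation of every index for both families from their
    symbolic edge partitions, an audit that compares the exact coefficients
    against published values and flags arithmetic errata, and reproduction of
    the published comparison grids. A small command-line front end exposes
    graph generation, index computation, grid reproduction and the audit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
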