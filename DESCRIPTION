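Package: homtree
Title: Persistent Homology via All-Order Spanning Trees and Critical Simplices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes homology of simplicial networks (clique complexes of
    graphs, Vietoris-Rips complexes of point clouds, or explicit
    triangulations) by searching all-order spanning trees of boundary
    matrices over GF(2). Every simplex is classified as a tree, paired, or
    cavity-generating (critical) simplex; the classification induces an
    optimal discrete Morse function whose critical simplices number exactly
    the Betti numbers, a nested filtration, and persistence barcodes.
    Representative cycles of cavities in every dimension are obtained by
    solving the spanning-tree/critical-simplex matrix equation over GF(2)
    or, in the oriented formulation, by an exact rational normal-equation
    solve. Includes cavity-shortening by iterated cycle addition, exhaustive
    optimal one-dimensional cavity search, and a Hodge-Laplacian nullity
    cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
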