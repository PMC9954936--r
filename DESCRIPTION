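Package: treph
Title: Extended Persistent Homology and Topological Layers for Graph Neural
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact extended persistent homology for vertex-filtered graphs,
    computed by Z2 boundary-matrix reduction over the ascending (sublevel)
    and descending (superlevel) passes, yielding the four diagrams Ord0,
    Ext0, Ext1 and Rel1 together with the full simplex pairing and the
    locating map from algebraic simplices to vertices.  On top of the
    engine, the package provides TREPH, a differentiable plug-in layer for
    graph neural networks that learns filter functions with a GIN-epsilon
    convolution, vectorizes diagram points with rational-hat coordinate
    functions, and aggregates each topological feature back to the graph
    nodes marking its birth and death; ablation variants based on ordinary
    persistence, a reverse-mode gradient tape, and a training harness for
    graph classification are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
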