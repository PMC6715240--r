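Package: gmlayout
Title: Grid- and Modularity-Based Layout of Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Draws biological networks on an integer grid while respecting
    their modular structure. Nodes are first partitioned into predefined or
    pseudo modules (multilevel modularity maximization), modules are placed
    as single points by minimizing a Manhattan-distance cost, each module is
    expanded into a disjoint square region sized for its members, and node
    positions are then optimized inside the regions with a
    reoptimization-after-perturbation heuristic. Includes layout-quality
    metrics (connectivity F-measure, relative edge length, edge-edge and
    node-edge crossing ratios), a planted-partition generator for synthetic
    benchmarks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
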