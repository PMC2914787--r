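Package: morphosim
Title: Agent-Based Speciation Simulator in a Two-Dimensional Morphospace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Individual-based evolutionary simulator in which organisms are
    points in a bounded two-dimensional morphospace, mate assortatively with
    their nearest phenotypic neighbour, and produce offspring whose trait
    coordinates fall within the parental range extended by a maximum mutation
    size. Fitness is read off a coarse random landscape (bilinearly
    interpolated) that either shifts gradually or is depleted by local
    population density under a conservation constraint. Species are detected
    each generation as reproductively isolated clusters (connected components
    of the who-mated-with-whom graph augmented with second-nearest
    neighbours). The package provides the full measurement layer (population
    and cluster time series, within-cluster diversity, population-cluster
    correlation, lineage tracing, mutation-size sweeps and competition among
    heritable mutation sizes), experiment orchestration, CSV/JSON writers and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
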