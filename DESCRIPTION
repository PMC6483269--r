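Package: evopaths
Title: Competing Evolutionary Paths in Growing Branching Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the emergence of a target cell type in a growing
    population as a multitype branching process spreading through a
    directed graph from a root to a target vertex.  Provides an exact
    continuous-time stochastic simulator with vertex-lineage tracking,
    small-transition-rate analytic approximations for the target hitting
    time and the distribution over seeding paths (path weights, median
    hitting times, time advantages between competing paths), and
    ready-made scenario builders for drug-resistance applications:
    imperfect drug penetration under mono- and combination therapy,
    resistance mechanisms in chronic myeloid leukemia, and the ordering
    of resistance mutations in bacteria.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
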