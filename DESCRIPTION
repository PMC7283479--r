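Package: ticknet
Title: Community Analysis of Tick-Host Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted bipartite networks from literature records of
    ticks and their vertebrate hosts and analyses them as interacting
    communities: Louvain modularity clustering and life-stage cluster
    switching, NODF nestedness, betweenness centrality, phylogenetic
    host-specificity (Faith's PD, mean pairwise distance with randomization
    nulls), and extinction-cascade resilience of clusters under intra-only
    and full-link configurations. Includes a synthetic-data generator with
    planted modules, stage-switching species and clade-restricted host use
    so that every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    vegan,
    picante,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
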