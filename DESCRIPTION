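Package: efnet
Title: Evolving Elementary-Functionome Networks of Loop Prototypes and
    Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and analyses time-resolved bipartite networks that link
    supersecondary loop prototypes to SCOP fold-family domains along a
    phylogenomic chronology. Transfers domain ages to loops under two
    age-transfer schemes, classifies prototypes as modular, contemporaneous-
    modular or non-modular, constructs cumulative time-event network series
    and directed one-mode projections, quantifies the per-event emergence of
    scale-free structure (discrete power-law maximum likelihood,
    Kolmogorov-Smirnov goodness of fit with bootstrap) and of hierarchical
    modularity (Newman-Girvan, fast-greedy and clustering-coefficient
    indices, scaled pairwise modularity matrices with Ward dendrograms),
    lays networks out as age-ordered waterfalls, and stitches loop sequences
    into time-ordered growing molecular intermediates. A synthetic-data
    generator with planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
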