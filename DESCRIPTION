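Package: cogevo
Title: Gene-Content Evolution from Ortholog Clusters: Gain-Loss
    Reconstruction, Pangenome Decomposition and Transfer Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying gene-content evolution across a set of
    genomes. Builds COG-style ortholog clusters from all-vs-all similarity
    tables via symmetric-best-hit triangles, decomposes pangenome
    commonality distributions into exponential cloud/shell/core components,
    fits a branch-specific two-state (absent/present) gain-loss model with
    a two-category family rate mixture by maximum likelihood, computes
    posterior probabilities of ancestral presence and of per-branch gain
    and loss events by the up-down algorithm, and derives downstream
    statistics of gene gain patterns, including two-gain pair exchange
    tables with a Poisson null. A synthetic-data generator with recorded
    ground truth supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
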