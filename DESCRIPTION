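Package: mirmrna
Title: Integrated miRNA-mRNA Differential Expression and Network Analysis
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for integrated microRNA and mRNA
    microarray analysis in a tumor-versus-normal design: empirical-Bayes
    moderated differential expression with fold-change/P/FDR threshold
    filters, unsupervised hierarchical clustering with Pearson correlation
    distance and average linkage, seed-region (8mer/7mer) target site
    prediction against 3'UTR sequences, anti-correlation filtering of
    predicted miRNA-target pairs, gene-set (GO/pathway) enrichment with
    Fisher's exact and chi-squared tests plus a paired-test run-level FDR,
    bipartite miRNA-GO and miRNA-mRNA networks ranked by degree, and
    cross-cohort direction-concordance confirmation. Includes a synthetic
    data generator with planted ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    ape
Config/testthat/edition: 3
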