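Package: epicross
Title: Case-Control DNA Methylation and Expression Analysis Across Cell Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential DNA methylation (Infinium 27K beta/M-value) and gene
    expression analysis for case-control studies profiled in several
    patient-derived cell types. Implements beta/M transforms and methylation-state
    binning, replicate and PCA quality control, per-probe linear modelling with
    empirical-Bayes variance moderation and Benjamini-Hochberg FDR, a Monte-Carlo
    test for the significance of k-way overlap between differential gene lists,
    gene-set over-representation and activation z-scores, seed-gene
    protein-protein-interaction subnetworks with a binomial Z enrichment test,
    directional methylation-expression concordance networks, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    data.table,
    igraph,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
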