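Package: omicsubtyper
Title: Multi-Omics Subgroup Discovery by Autoencoder Integration, Consensus
    Clustering and Classifier Fusion
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for molecular subgroup identification from
    multi-omics data (mRNA, miRNA, DNA methylation, protein expression).
    Per-omic preprocessing (sparsity filters, KNN imputation, variance
    selection, min-max scaling) and feature stacking; non-linear integration
    through an under-complete autoencoder with a PCA baseline; consensus
    K-means clustering with model selection by the proportion of ambiguously
    clustered pairs (PAC); subgroup characterization by Kaplan-Meier and
    log-rank survival analysis, ANOVA/Tukey and methylation differential
    testing, and Fisher enrichment of mutations and copy-number alterations;
    and two-level classifier fusion (SVM-RBF, random forest, feed-forward
    network base learners combined by weighted-probability or stacked
    meta-learners) to assign subgroups to new, possibly single-omic, samples.
    Includes a seeded synthetic multi-omics generator so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cluster,
    limma,
    matrixStats,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
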