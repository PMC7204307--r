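Package: cinscore
Title: Chromosomal Instability Scoring from Copy-Number, Mutation and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromosomal instability (CIN) in tumor cohorts.
    Classifies copy-number segments into gain/loss and arm-level (broad)
    versus focal events and computes per-sample genomic alteration scores
    (broad-CNA, focal-CNA, tumor mutational burden, fusion score);
    computes single-sample gene-signature activation scores (CIN70 and the
    seven-gene PC-CIN mitotic signature) by a standardized Z-score method;
    calls differentially expressed genes with a permutation-based
    integrative test and intersects calls across cohorts; runs gene set
    enrichment analysis with a Kolmogorov-Smirnov running-sum statistic,
    random-gene-set permutation p-values and leading-edge extraction; and
    fits a PCA + Gaussian-kernel SVM classifier of metastasis stage with
    ROC/AUC evaluation. A synthetic cohort generator with a latent
    per-sample CIN level makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    e1071,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    pROC,
    jsonlite
Config/testthat/edition: 3
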