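Package: humoclust
Title: Cross-Species Disease Positioning of Human and Mouse Tumour Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of human and mouse bulk RNA-seq cohorts to
    discover shared transcriptional disease subtypes ("HuMo" clusters).
    Counts are variance-stabilized per species with a closed-form
    negative-binomial transform, reduced to one-to-one orthologs, centred
    within sample, and factorized by SVD into a rank-r human latent space
    into which mouse samples are projected. Communities on the joint
    k-nearest-neighbour sample graph are detected with the Louvain method.
    Clusters are characterized by single-sample gene set enrichment
    (ssGSEA), maximal-enrichment subclass assignment, Nearest Template
    Prediction with permutation significance, Fisher exact association
    panels with log odds ratios, and Kaplan-Meier/log-rank survival
    comparisons. Includes a negative-binomial paired-cohort simulator with
    planted subtype structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    survival,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    DESeq2,
    withr,
    cluster
Config/testthat/edition: 3
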