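Package: sexbias
Title: Sex Biases in Disease Incidence and Tissue Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and relating sex biases in disease
    incidence and in bulk tissue gene expression. Implements log2 incidence
    rate sex bias (IRSB) measures with estimators that complete missing
    measures from partially reported study quantities, availability
    partitioning and estimator validation, tissue- and country-matched
    pairing of autoimmune-disease and cancer incidence points with
    correlation tests, per-tissue expression sex bias (ESB) and gene-set
    activity sex bias (ASB) from TPM matrices, per-gene across-tissue
    ESB-IRSB correlations, preranked gene set enrichment analysis with a
    gene-label permutation null, first-order partial correlation, and a
    synthetic-data generator with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse,
    yaml
Config/testthat/edition: 3
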