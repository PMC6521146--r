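Package: yylasso
Title: Sample-Specific Lasso Models of Yin and Yang Gene Regulation in Breast Cancer Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative regulatory analysis of tumor transcriptomes. Fits a
    lasso regression model per tumor that explains tumor-versus-normal log2
    expression fold changes of strongly up- (Yin) and down-regulated (Yang)
    genes from gene-level copy number, promoter methylation, transcription
    factor binding-site counts and miRNA binding-site counts. Regulators are
    scored per molecular subtype by the increase in total squared loss when
    their coefficients are zeroed, calibrated against a permutation null with
    Benjamini-Hochberg control. Includes promoter-window ChIP-seq peak
    annotation, hypergeometric gene-set enrichment of regulator targets,
    regulator-target network export, Yin/Yang mean-ratio (YMR) and Cox-based
    combined risk score (CRS) prognostic signatures with Kaplan-Meier and
    log-rank evaluation, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    parallel,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    rtracklayer,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
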