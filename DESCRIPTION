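Package: immunoscape
Title: Spatial Scoring of Lymphocyte Infiltration in Tumour Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cancer-immune spatial interaction from classified
    cell coordinates of H&E tumour sections. Estimates a cancer-cell
    intensity surface with a quartic (biweight) kernel, derives each
    lymphocyte's spatial proximity to cancer, discovers intratumour,
    adjacent-tumour and distal-tumour lymphocyte classes by univariate
    Gaussian-mixture clustering with BIC model selection and resampling
    stability analysis, and summarises each tumour by the intratumour
    lymphocyte ratio (ITLR) and companion scores. Downstream tools link
    scores to outcome (percentile cut-off scans, Kaplan-Meier/log-rank,
    Cox models, bootstrap stability) and to gene expression (correlation
    with Storey-type q-values, co-expression module discovery,
    hypergeometric gene-set enrichment). A synthetic-data module generates
    tumour point patterns, survival tables and expression matrices with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
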