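Package: gcbmi
Title: Multi-Omics Biomarker Identification for Tumor/Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene-expression and DNA-methylation matrices from
    unpaired tumor/normal cohorts to identify candidate cancer biomarkers.
    The pipeline applies mutual-information pre-screening, fold-change plus
    variance-gated two-sample t-tests with Benjamini-Hochberg false discovery
    rate control per modality, intersects the differential gene sets across
    modalities, expands training data by Cartesian-product pairing of
    same-label samples from the two modalities, and evaluates the selected
    genes with a deep neural network classifier under stratified five-fold
    cross-validation. A seeded synthetic-cohort generator with planted,
    cross-modality-concordant differential genes makes every stage testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
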