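Package: sulfscan
Title: Pan-Cancer Expression, Survival and Tumor-Stroma Attribution Statistics
    for the Heparan 6-O-Endosulfatases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable statistical pipeline for studying the extracellular
    heparan sulfate 6-O-endosulfatases SULF1 and SULF2 (or any gene pair)
    across cancer cohorts: paired and unpaired differential expression on
    log2-transformed abundances with fold-change plus false-discovery-rate
    significance calling; Kaplan-Meier, log-rank and multivariable Cox
    proportional-hazards survival analysis with a constrained minimal-p-value
    expression cutpoint search; permutation tests for enrichment of
    gene-signature correlations (e.g., cancer-associated-fibroblast
    signatures); single-cell percent-positivity and cell-type attribution
    statistics; and paired patient-versus-xenograft comparisons quantifying
    stromal loss. Seedable synthetic-data generators emulate each input so
    the full workflow is testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
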