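Package: protlfq
Title: Label-Free LC-MS Proteomic Quantification and Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for label-free LC-MS differential protein
    expression analysis of case-control biofluid studies: cross-run feature
    alignment with retention-time, charge and fragment-fingerprint matching,
    log2 transformation and quantile normalization, peptide-to-protein
    roll-up, per-protein mixed-model ANOVA with a nested random sample
    effect, signed fold-changes, Benjamini-Hochberg q-values, coefficient-of-
    variation summaries and spike-in quality control, peptide-confidence
    based priority classification, linear-discriminant biomarker panel
    selection with leave-one-out forward search, and multiple-reaction-
    monitoring (MRM) transition list design and relative quantification.
    Includes a synthetic-data generator reproducing the variance structure
    of replicated case-control LC-MS designs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    MASS,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
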