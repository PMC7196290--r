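Package: ctcdx
Title: Liquid-Biopsy Analysis of Circulating Tumor Cells in EGFR-Mutant Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for circulating tumor cell (CTC)
    liquid-biopsy studies in non-small cell lung cancer. Provides single-cell
    qRT-PCR Ct preprocessing (quality filtering, undetected-value imputation,
    GAPDH delta-Ct normalization, Z-scoring), per-cell epithelial/mesenchymal
    (EMT) scoring, unsupervised heterogeneity analysis (hierarchical
    clustering, t-SNE, Spearman correlation matrices with Bonferroni
    adjustment), CTC-count kinetics against radiographic response, Kaplan-Meier
    survival stratification by an optimized baseline-count cutoff, and
    tissue-versus-CTC mutation concordance, together with a synthetic-cohort
    generator so every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    survival,
    Rtsne,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
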