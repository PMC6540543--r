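Package: gliometa
Title: Multi-Study Differential-Expression Meta-Analysis for Glioblastoma Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated meta-analysis of multi-study gene expression cohorts for
    screening glioblastoma-specific differentially expressed genes. Provides a
    synthetic multi-study cohort generator with planted pan-glioma and
    GBM-specific effects and linked survival outcomes; per-study moderated-t
    statistics with pooled permutation p-values and Hedges' g effect sizes; four
    p-value combination methods (Fisher's sum of logs, maxP, roP, adaptively
    weighted) and DerSimonian-Laird random-effects effect-size pooling with
    Benjamini-Hochberg FDR control; a dual-method / training-validation /
    subtype-specificity DEG selection cascade; and downstream
    median-dichotomized Kaplan-Meier and log-rank survival analysis, ROC
    diagnostics, Kruskal-Wallis tests, hypergeometric over-representation
    analysis, immunoreactivity scoring and relative qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
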