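Package: tmcell
Title: Tumor-Matching T Cell Identification and Marker Gate Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies "tumor-matching" (TM) CD8 T cells in blood by exact
    T-cell-receptor (TCR) clonotype matching against paired tumor samples, and
    discovers single and combinatorial cell-surface marker gates that enrich
    them. Implements quality-control filters and log TP10K normalization for
    10x-style count matrices, clonotype assignment from contig annotation
    tables, a 39-threshold ROC/AUC grid, an exact XL-minimal-hypergeometric
    marker test with Benjamini-Hochberg correction, consensus marker ranking
    across samples, enumeration and pareto/penalty selection of monotone
    boolean marker gates, bootstrap confidence intervals and permutation
    empirical p-values, and a negative-binomial synthetic-data generator with
    planted clonal structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
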