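Package: iccdissect
Title: Dissecting Intra-Pair Gene Expression Variability in Paired Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting intra-pair gene-expression variability in
    paired tumor samples (synchronous and metachronous bilateral breast
    cancers, primaries with their local recurrences) into genetic-background
    and time/microenvironment components. Computes a per-gene agreement
    intraclass correlation coefficient (ICC) from a two-way ANOVA
    variance-component decomposition, stratifies it by gene signatures
    (intrinsic/PAM50 versus stromal), and compares ICC distributions across
    pair groups. Includes expression-matrix input/output and preprocessing
    (detection filtering, quantile normalization, IQR filtering, variant-probe
    counting, bimodal receptor-status calling) and a variance-component
    simulator of paired-tumor cohorts with closed-form population ICCs for
    estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    mclust,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
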