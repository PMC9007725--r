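Package: methdmr
Title: Region-Level Methylation Quantification and Differential
    Methylation Analysis for Targeted Bisulfite Capture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing targeted bisulfite capture methylation
    data at the level of predefined genomic regions: collapsing
    cytosine-level methylated/total read counts to region-level count
    matrices, computing methylation fractions (beta values), filtering
    regions by all-sample coverage, calling differentially methylated
    regions (DMRs) between two tumour groups via log2 fold enrichment of
    group mean betas with per-region t-tests and Bonferroni correction,
    classifying DMRs into high/low magnitude classes, annotating regions
    with CpG-centric (island/shore/shelf/open sea) and genic contexts,
    Mann-Whitney group-distribution contrasts, and clinical cohort
    descriptive statistics with censored and missing value handling.
    Includes a beta-binomial synthetic-data generator with planted
    differential effects so that the whole pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
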