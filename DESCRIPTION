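Package: inflamethyl
Title: Differential Methylation, Enhancer Enrichment and Target Linking for
    Chronically Inflamed Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An epigenome-wide analysis toolkit for comparing DNA methylation
    between chronically inflamed and healthy tissue on beta-value arrays.
    Calls differentially methylated CpGs (Welch test, Benjamini-Hochberg FDR,
    delta-beta effect filter), tests enrichment or depletion of differential
    probe sets at regulatory feature sets by array-background permutation,
    defines putative enhancers as DNase hypersensitive sites lacking H3K4me3,
    links hypermethylated enhancers to target gene promoters by windowed
    pairwise correlation of DNase signal across cell lines, measures
    directional overlap of differential probe sets between cohorts with the
    hypergeometric test, and provides the surrounding context statistics
    (coverage-filtered RRBS methylation partitioned by binding peaks with
    Kolmogorov-Smirnov testing, MS-HRM category analysis with Fisher's exact
    test, Spearman methylation-expression correlation, Mann-Whitney group
    comparison). A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is testable at desk scale.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
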