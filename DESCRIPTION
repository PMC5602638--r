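Package: valleytf
Title: Transcription-Factor Discovery from Histone-Acetylation Valleys and
    Temporal Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects "valleys" (local dips) in histone-acetylation ChIP-seq
    coverage, scores transcription-factor binding-site motif enrichment within
    valley-defined active promoter regions over a stimulation time course, and
    associates motifs with temporal gene-expression clusters by time-lagged
    correlation of motif enrichment scores with cluster-median expression.
    Includes a random-gene-set ChIP-seq enrichment test for validating
    predicted regulators and a fully synthetic data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
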