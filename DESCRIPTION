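Package: cortexmeth
Title: Cell-Type-Resolved Analysis of Developing Brain DNA Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing data
    from sorted neuronal and glial nuclei across postnatal development:
    per-cytosine report input and filtering, local-likelihood smoothing,
    methylome segmentation into unmethylated and low-methylated regions,
    partially methylated domains and DNA methylation valleys, differentially
    methylated position and region detection by bump hunting with
    permutation-based family-wise error control, decomposition of cell-type by
    age interaction regions into developmental trajectory clusters,
    context-stratified methylation autocorrelation, and cytosine-level
    methylation-expression association scans. Includes a synthetic whole-genome
    bisulfite data generator with a machine-readable truth ledger so every
    stage can be exercised and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
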