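Package: chickclock
Title: Multi-Tissue DNA Methylation Clocks for Broiler Chicken
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying low-methylated-region (LMR) based
    DNA methylation clocks for the short-lived broiler chicken. Covers the
    full workflow from per-CpG bisulfite methylation calls (methratio-style
    tables or bedGraph pairs) through coverage filtering, LMR segmentation
    with shuffle-based FDR calibration, tissue-offset normalization, and
    elastic-net age regression with cross-validation, to differential
    methylation between age groups, clock-marker feature enrichment, and
    epigenetic age-acceleration testing. Includes a beta-binomial synthetic
    methylome generator with full ground truth so every pipeline stage can be
    validated without sequencing data.
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
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
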