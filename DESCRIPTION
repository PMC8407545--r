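Package: plasmafrac
Title: Tumor Fraction Estimation and Classification from Plasma cfDNA Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for distinguishing malignant peripheral nerve
    sheath tumor (MPNST) from benign plexiform neurofibroma (PN) using
    ultra-low-pass whole-genome sequencing of plasma cell-free DNA. Provides
    in silico fragment-size selection (90-150 bp), binned read-count
    copy-number estimation with GC/mappability bias correction and
    panel-of-normals normalization, tumor-fraction inference via a
    two-component mixture model with hidden-Markov copy-number states,
    ROC/Youden-index cutpoint classification with leave-one-out
    cross-validation, and serial tumor-fraction versus imaging (RECIST SLD)
    monitoring. Includes a seeded synthetic cfDNA cohort generator that
    emulates the statistical structure of an NF1 surveillance cohort so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
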