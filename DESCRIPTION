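Package: tgctsig
Title: Somatic Mutation and Copy-Number Signature Analysis for Testicular
    Germ-Cell Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for multi-cohort testicular germ-cell tumour
    (TGCT) genomics: harmonisation and hard filtering of multi-caller somatic
    variant calls, tumour mutation burden and mutation multiplicity/clonality,
    COSMIC-style 96-channel SNV signature fitting, copy-number feature
    extraction with mixture-model posterior encoding and non-negative matrix
    factorisation into copy-number signatures, arm-level aneuploidy scoring,
    covariate-adjusted association testing, and longitudinal force-calling
    with minimum-event copy-number phylogenies. Includes a seed-reproducible
    synthetic cohort generator carrying ground-truth labels for every
    statistical structure the pipeline assumes, used throughout the test
    suite for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    ape,
    pracma,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
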