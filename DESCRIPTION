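Package: cytovar
Title: Association Screening and Variance Decomposition for Stimulated
    Cytokine Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing inter-individual variability in
    cytokine secretion after standardized whole-blood stimulation.
    Provides induction profiling of stimulated-versus-control cytokine
    concentrations, screening of donor variables against induced
    cytokines with nested-linear-model likelihood-ratio tests and
    Benjamini-Yekutieli false-discovery-rate control,
    covariate-elimination mediation screening over immune-cell, plasma
    protein and CpG methylation panels, response protein quantitative
    trait locus (pQTL) mapping with conditional analysis and
    genotype-by-smoking interaction tests, and Shapley (LMG)
    decomposition of explained variance. A seeded synthetic-cohort
    generator with a ground-truth ledger of planted effects supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
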