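Package: animalfluency
Title: Item-Level Animal Fluency Analysis and Abundant Class Knowledge Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for item-level analysis of semantic (animal) verbal fluency
    transcripts. Detects within-class series of consecutively recalled animals
    tolerating at most one interruption, classifies participants with abundant
    animal class knowledge at configurable cutoffs, and runs the accompanying
    cohort comparison statistics (Welch t-tests, Yates-corrected chi-square,
    covariate-adjusted linear regression, Benjamini-Hochberg false discovery
    rate control). Includes transcript scoring rules (repetitions, plurals
    after singulars, proper names, non-target language), class imputation for
    plus-sign placeholders, and a synthetic-cohort generator emulating
    two-minute animal fluency output with clustered class runs so the whole
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
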