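Package: polyrisk
Title: Joint Common- and Rare-Variant Liability Analysis for Complex Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how common polygenic variation and rare
    damaging variants combine to confer liability to a complex disorder such
    as autism spectrum disorder. Implements cluster-aware G-BLUP genomic
    prediction with a leave-matched-pair-out training plan, genomic
    relationship matrices standardized by empirical-Bayes cluster-specific
    allele frequencies, pruning-and-thresholding polygenic risk scores, a
    weighted genomic risk score, carrier classification for potentially
    damaging variants, the liability-threshold calculus linking prevalence
    and relative risk to group mean liabilities, and a structured-population
    cohort simulator for end-to-end validation without restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
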