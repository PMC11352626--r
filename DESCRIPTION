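Package: cureplateau
Title: Cure-Fraction Plateau Survival Modelling and Biomarker Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative immunohistochemistry scoring
    (immunoreactive score and tiered percent-positivity calls),
    Kaplan-Meier estimation of right-censored time-to-event data, fitting
    of an exponential decay-to-plateau (cure-fraction) survival model,
    comparison of pooled versus biomarker-stratified models by AIC,
    evidence ratios and the extra-sum-of-squares F test, single-sample
    gene-set enrichment with rank normalisation, reduced major axis
    regression, and a seeded synthetic-cohort generator that emulates the
    joint marker distribution, cure-fraction survival and censoring
    structure of a Hodgkin-lymphoma cohort. All user-facing functions
    take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
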