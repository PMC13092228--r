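Package: shoretrends
Title: Detection and Attribution of Biodiversity Change in Long-Term
    Rocky-Shore Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-investigator, multi-decade intertidal
    survey data: harmonization and filtering of raw quadrat records,
    coverage-standardized Hill diversity (richness, Hill-Shannon,
    Hill-Simpson) and evenness, reduction of daily sea-surface temperature to
    a pre-survey maximum-temperature covariate, Bayesian linear and
    Gaussian-process models for detecting temporal trends across investigator
    eras and attributing diversity change to temperature, a
    language-of-evidence grading of posterior results, per-taxon log response
    ratios against a historical baseline classified by geographic range, and
    a synthetic-data generator with the statistical structure the analysis
    assumes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    coda,
    digest,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
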