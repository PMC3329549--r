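Package: breedfail
Title: Maternal Breeding-Failure Risk Across the Finnish Demographic Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the maternal risk of breeding failure
    (raising none of one's children to adulthood) relates to lifetime
    fertility and age at first reproduction across the demographic
    transitions, as observed in Finnish church-register cohorts with first
    births between 1880 and 1979. Provides a calibrated synthetic cohort
    generator with realistic record incompleteness, the weighted per-mother
    estimators of offspring survival, breeding probability and lifetime
    reproductive success used with incompletely tracked pedigrees, the
    breeding-failure risk statistic (1 - s)^q with its required-fertility
    calculator, and decade-stratified weighted generalized linear models
    with likelihood-ratio backward stepwise simplification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
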