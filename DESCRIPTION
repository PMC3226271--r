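Package: pgsa
Title: Placebo Group Simulation for Presymptomatic Alzheimer's Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive models of cognitive decline in mild cognitive impairment
    (MCI) for the placebo group simulation approach (PGSA): a square-root-scale
    endpoint regression for the modified ADAS-cog at 24 months with AIC-based
    term selection, a random-intercept/random-slope mixed model for a
    neuropsychological composite (NP-Batt) over 36 months, virtual-placebo
    simulation from fitted-model artifacts, analytic and Monte-Carlo power for
    course-altering treatment effects, a Gaussian-copula synthetic cohort
    generator emulating published ADNI-MCI baseline marginals, and model
    validation tools (subject-level k-fold cross-validation, variance inflation
    factors, observed-versus-simulated distribution comparison).
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
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
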