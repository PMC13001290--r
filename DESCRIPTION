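Package: hldist
Title: Healthy Longevity Distributions from Prevalence and Mortality Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives full distributions of healthy longevity (the age at
    exit from the healthy state) for people healthy at age 60, from
    age-specific health prevalence and mortality schedules.  The first
    three statistical moments of healthy lifespan are computed with a
    Markov chain with rewards; the complete discrete exit-age
    distribution on ages 60-90 is reconstructed by maximum entropy
    subject to those moments; male-female (or any two-population)
    comparisons use the healthy-lifespan outsurvival statistic and the
    Hellinger distance; sampling uncertainty is propagated by a
    survey-weighted bootstrap with percentile confidence intervals.  A
    synthetic-data module emulates survey microdata and period life
    tables so every stage is testable without restricted data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
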