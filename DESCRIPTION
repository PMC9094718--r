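Package: demfrailsim
Title: Dynamic Microsimulation of Dementia and Frailty Burden in an
    Ageing Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based microsimulation of joint dementia and frailty
    burden in a population aged 60 years and older. Simulates half-year
    first-order Markov transitions across eleven chronic conditions,
    functional status, depression and self-reported health, with
    education-stratified mortality and stochastic entry cohorts; classifies
    dementia, mild cognitive impairment and physical frailty through
    calibrated latent-probability (multivariate probit and logistic) models
    with prevalence-matched thresholds; partitions period life expectancy at
    age 65 into years lived with and without each condition by the Sullivan
    method; projects formal long-term-care, health-care and informal-care
    costs; and quantifies uncertainty with bootstrap percentile intervals.
    Ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
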