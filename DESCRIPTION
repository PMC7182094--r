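Package: twinherit
Title: Liability-Threshold Twin Models of Heritability and Familial
    Co-Aggregation for Registry-Ascertained Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classical twin analysis of binary, registry-ascertained
    phenotypes. Implements rule-based case ascertainment from coded health
    register event streams, cohort exclusion cascades, prevalence and
    probandwise concordance statistics, maximum-likelihood tetrachoric
    correlations on twin pair tables, joint monozygotic/dizygotic
    liability-threshold variance-component models (ACE, ADE, AE, CE, E) with
    AIC model selection and profile-likelihood intervals, an individual-level
    liability model with inverse-probability-of-censoring weighting for left
    truncation and right censoring, cross-twin co-aggregation analysis via
    age-scale Cox regression with time-varying co-twin exposure and
    pair-clustered robust variance, and a synthetic twin-cohort generator
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
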