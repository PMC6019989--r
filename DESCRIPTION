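Package: gestloss
Title: Gestational-Age-Interval Pregnancy Loss Rates, Cohort Projection,
    and Risk-Factor Models for Pregnancy Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing early pregnancy loss in prospective
    population-based pregnancy registries with staggered enrollment.
    Estimates per-1000 miscarriage and medical-termination (MTP) rates in
    gestational-age intervals using left-truncation-aware risk sets and a
    competing-event denominator-exclusion convention; projects a
    hypothetical cohort of ongoing pregnancies through sequential
    miscarriage, MTP, stillbirth and neonatal-death decrements to live
    infants at 28 days; fits adjusted log-link binomial relative-risk
    models with a cluster random intercept for maternal risk factors; and
    generates synthetic registries with known ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
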