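Package: meowsri
Title: Obstetric Risk Identification and Modified Early Obstetric Warning
    Score Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a combined bedside instrument for parturients: a
    Risk Identification (RI) checklist that grades hemorrhage,
    preeclampsia/eclampsia and sepsis risk as low/moderate/high, and a
    Modified Early Obstetric Warning Score (MEOWS) that converts seven
    routine physiologic observations into 0-3 point bands with
    track-and-trigger escalation tiers. Provides cohort-level triage, a
    feasibility (form-completeness) audit, diagnostic-performance
    evaluation of the moderate/high dichotomy against a composite
    morbidity outcome (sensitivity, specificity, predictive values,
    accuracy, Katz relative-risk confidence intervals, chi-square
    association), Likert experience summaries, and a reproducible
    synthetic parturient-cohort generator for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
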