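Package: vsalert
Title: Traffic-Light Vital Signs Early Warning, Blood Pressure Device
    Validation Statistics and Threshold-Outcome Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the traffic-light vital signs early warning system
    used on low-cost semiautomated blood pressure devices for pregnant
    women in low-resource settings: Shock Index (pulse over systolic blood
    pressure) and blood pressure thresholds map each reading to a green,
    yellow or red alert, with shock prioritised over hypertension.
    Companion statistics cover paired device-versus-reference validation
    (mean and standard deviation of differences against ISO bounds, BHS
    cumulative-percentage grading, arm-circumference strata), evaluation of
    alert tiers against binary adverse outcomes (per-tier risk, risk
    ratios, diagnostic metrics, Woolf odds-ratio confidence intervals) and
    pre/post-intervention proportion comparisons. Seed-controlled
    generators simulate mixed obstetric populations, paired measurement
    studies with cuff-related bias, outcome cohorts with designed per-tier
    risks, and pre/post datasets. A command-line interface binds the
    modules for file-based workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
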