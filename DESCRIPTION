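Package: rxmsm
Title: Per-Protocol Comparative Effectiveness from Prescription Claims with
    Stabilized Inverse-Probability Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds new-user (inception) cohorts of antihypertensive
    monotherapy initiators from raw pharmacy dispensing records, converts
    follow-up into 180-day person-periods carrying two adherence measures
    and time-varying comorbidity drug flags, ascertains a drug-proxy
    cardiovascular outcome, and estimates comparative effectiveness with
    stabilized inverse-probability-of-treatment weights, time-varying Cox
    regression, and weighted Kaplan-Meier curves. Includes a discrete-time
    simulator of prescription databases with planted hazard ratios and
    confounding by indication so the whole pipeline can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    nnet,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
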