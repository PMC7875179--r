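Package: psyriskscreen
Title: Transdiagnostic Psychosis Risk Calculator Screening and Alert
    Workflow Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the published transdiagnostic, clinically-based
    psychosis risk calculator (a Cox proportional-hazards linear predictor
    over age, gender, ethnicity, index diagnosis cluster and an age-by-gender
    interaction) together with the automatic electronic health record
    screening loop it was deployed in: weekly eligibility screening with
    predictor-missingness re-checks, detection at a configurable two-year
    risk threshold, a clinician alert-escalation state machine
    (email/email/email/phone), and the feasibility statistics used to
    evaluate such a deployment (clinician adherence, Fisher exact odds
    ratios, Kaplan-Meier cumulative incidence with Greenwood confidence
    intervals, log-rank tests, Welch t-tests from summary statistics,
    Harrell's concordance index). A synthetic cohort generator produces
    electronic-health-record-like intake streams with realistic category
    frequencies, predictor missingness and Cox-model-driven outcomes, and a
    study runner wires generation, screening, alerts and statistics into a
    single reproducible, seeded run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
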