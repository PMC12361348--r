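Package: lylcohort
Title: Life-Years Lost Before a Cutoff Age with Time-Varying Diagnosis Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates life-years lost (LYL) before a cutoff age associated
    with time-varying diagnosis exposures in open cohorts, on the age
    timescale with delayed entry. Provides ICD-10 code-range phenotyping of
    mental-disorder groups and causes of death, episode splitting at first
    diagnosis with carry-forward of prevalent diagnoses, left-truncated
    Kaplan-Meier and Aalen-Johansen estimation, exact step-function
    integration of conditional LYL decomposed by cause of death, stratified
    pooling, and nonparametric bootstrap confidence intervals. Includes a
    parameterized illness-death cohort simulator with analytic ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
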