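Package: pulmowalk
Title: Adaptive Walking Rehabilitation Regimens and Trial Analytics for
    Home-Based Pulmonary Telerehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for home-based pulmonary rehabilitation in chronic
    obstructive pulmonary disease (COPD): deterministic state machines for
    fixed-distance and Borg-feedback interactive walking regimens with
    6-minute walk test (6MWT) based intensity initialization, in-session
    pulse-oximetry (SpO2) desaturation alerting, telemonitoring compliance
    and patient-flagging analytics, stratified permuted-block randomization,
    sample-size and Monte-Carlo power calculations, and one-way and
    repeated-measures ANOVA of visit outcomes. A seeded synthetic COPD
    cohort simulator generates walking-session telemetry, Borg responses,
    desaturation events, adherence, dropout, and visit outcomes so the full
    pipeline runs end to end without patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
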