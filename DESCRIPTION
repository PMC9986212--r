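Package: cbclscreen
Title: Construction and Validation of CBCL-Based Screening Subscales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates screening subscales from 120-item
    parent-rated child-behavior inventories of the CBCL 6-18 type.
    Provides a packaged item registry with subscale set algebra,
    a multi-informant ordinal cohort simulator with planted group
    effects, per-item informant-nested mixed models with an
    ASD-versus-comparison-group voting rule, a clinician-expert
    vote-threshold rule, raw-score scoring with informant averaging,
    Cronbach's alpha with interpretation bands, ROC/AUC machinery with
    DeLong paired and Hanley-McNeil independent curve comparisons, and
    stratified subclinical/clinical cut-off construction, orchestrated
    as a development plus cross-validation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
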