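Package: nphequiv
Title: Non-Inferiority and Equivalence Testing for Survival Curves Under
    Non-Proportional Hazards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric framework for testing non-inferiority and equivalence
    of two survival curves without assuming proportional hazards. Provides
    censored-data maximum likelihood estimation for six parametric survival
    families, delta-method and parametric-bootstrap pointwise confidence
    bands for the survival-curve difference and the log hazard ratio,
    pointwise and interval-wise intersection-union tests, a
    Kaplan-Meier/Greenwood non-parametric comparator, and a Monte-Carlo
    harness for coverage, type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
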