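Package: periodsurv
Title: Period-Analysis Relative Survival for Registry Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Actuarial life-table estimation of observed, expected (Ederer II)
    and relative survival for cancer-registry cohorts under cohort or period
    analysis with delayed entry, with Greenwood standard errors, ICSS-style
    age standardization, and model-based projection of future-period 5-year
    relative survival from a generalized linear model on conditional 1-year
    relative survival. Includes readers for case-listing and population
    life-table CSV exports and a synthetic registry generator with known
    excess-hazard structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
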