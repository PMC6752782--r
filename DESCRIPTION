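Package: robagree
Title: Convergent Validity Between Trial Risk-of-Bias Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between two risk-of-bias instruments rated
    on the same randomized trials nested in systematic reviews: the Cochrane
    risk-of-bias tool (three-level item ratings) and the PEDro scale (binary
    items). Provides rating-table ingestion with duplicate-trial resolution,
    dichotomization schemes for the "unclear" category, instrument summary
    scores, Cohen's kappa and percent exact agreement on k-by-k tables,
    one-way random-effects ICC(1,1), review-clustered bootstrap confidence
    intervals, a threshold-agreement matrix, between-review reliability, a
    contingency-table reconstruction utility for published marginals, and a
    synthetic-data generator with analytically computable expected agreement.
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
    e1071
Config/testthat/edition: 3
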