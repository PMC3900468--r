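Package: anuadri
Title: Self-Report Dementia Risk Index Scoring and Cohort Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ANU-ADRI, an additive self-report risk index for
    Alzheimer's disease built from evidence-synthesis point weights, together
    with the statistical pipeline used to validate point-based risk indices in
    longitudinal cohorts: complete-case filtering, c-statistics with DeLong
    confidence intervals (overall, by sex, by outcome, and on a common variable
    subset), within-study score quartiles, incidence per 1000 person-years,
    Cox proportional-hazards quartile hazard ratios with a linear trend test,
    an age-split quartile comparison, and a CAIDE comparator index. A seeded
    synthetic-cohort generator emulates the marginal risk-factor frequencies
    and follow-up structure of the published validation cohorts so the whole
    pipeline is testable without access to participant-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
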