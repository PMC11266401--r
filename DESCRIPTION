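Package: kmsacost
Title: Censoring-Adjusted Attributable Healthcare Costs from Matched Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating healthcare resource utilisation (HRU) and
    costs attributable to a disease from administrative claims, using a
    matched-cohort design with Kaplan-Meier sample average (KMSA) adjustment
    for administrative censoring. Implements new-case identification from
    diagnosis and procedure claims, exact 1:10 matching on age, sex and
    region, baseline comorbidity flagging, partitioning of follow-up into
    observation periods, two-part regression models (logistic use model plus
    log-link GLM for positive amounts) with recycled predictions, survival
    weighting of per-period means, and bootstrap confidence intervals for
    cumulative and incremental cost estimates. A calibrated synthetic claims
    generator reproduces the statistical structure the estimator assumes, so
    the whole pipeline can be exercised without access to confidential
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
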