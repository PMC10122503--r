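Package: smokesurg
Title: Smoking Status Extraction from Clinical Text and Postoperative
    Complication Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for studying smoking as a risk factor
    for 90-day postoperative complications in a surgical registry. Includes
    a seed-reproducible synthetic-data generator for Finnish-style
    smoking-status sentences and a confounded surgical cohort; a hashed
    bag-of-n-grams linear text classifier with per-class abstention
    thresholds tuned for precision; a most-recent-unless-never rule that
    collapses timestamped status notes into one preoperative smoking status
    per surgery; Charlson comorbidity index computation from ICD-10 codes;
    90-day composite and critical (Clavien-Dindo IV-V) outcome flags; and
    unadjusted/adjusted logistic-regression odds ratios with partial Wald
    chi-squared and Shapley-value variable importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
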