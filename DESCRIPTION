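Package: claimsir
Title: Claims-Based Inadequate-Response Phenotyping and Cost Analysis for
    Biologic DMARD Initiators in Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing biologic disease-modifying antirheumatic drug
    (bDMARD) response in rheumatoid arthritis from administrative claims in
    the style of Taiwan's National Health Insurance Research Database (NHIRD).
    Provides new-user cohort selection with washout and attrition reporting, a
    five-criterion claims-based inadequate-response classifier (proportion of
    days covered, biologic switch or add, new conventional DMARD,
    glucocorticoid joint injections, oral glucocorticoid dose increase), a
    Deyo-mapped Charlson comorbidity index, annualized healthcare resource use
    and direct-cost summaries with currency conversion, medication switching
    analyses, and a synthetic claims generator with planted per-patient ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    IRanges,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
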