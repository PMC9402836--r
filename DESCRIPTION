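Package: mishf
Title: Heart Failure Clinical Stability Scoring and Referral Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Maastricht Instability Score - Heart Failure
    (MIS-HF), an additive 33-item questionnaire that stratifies chronic heart
    failure outpatients into a clinically stable group (total score 0-2,
    eligible for referral to primary care) and an unstable group (score 3 or
    more, requiring specialist care). Provides the full scoring engine with
    auditable thresholds, unit conversions for NT-proBNP and haemoglobin,
    contingency-table odds ratios with Woolf confidence intervals and Wald
    tests, logistic regression by iteratively reweighted least squares,
    inter-rater reliability statistics (Cohen's kappa, intraclass correlation,
    Cronbach's alpha), a synthetic cohort generator for end-to-end testing
    without patient data, and a command-line pipeline over CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
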