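Package: gscore
Title: Tumor Growth Rate (g-Score) Modeling and Survival Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-subject estimation of tumor growth (g) and regression (d)
    rates from longitudinal sum-of-diameters tumor burden using four
    bi-exponential kinetic models (dx, gx, gd, gd-phi), with AIC- and
    p-value-based model selection, g-score and tumor doubling time
    extraction, and cohort-level association of g with overall and
    progression-free survival (quartile Kaplan-Meier and Cox analyses,
    Harrell concordance against RECIST-style response, early-look interim
    analyses). Includes a clinical-trial trajectory simulator with known
    kinetic ground truth and g-linked survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
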