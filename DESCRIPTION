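Package: camagree
Title: Method Agreement Analysis for Repeated Binary Delirium Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agreement analysis for two binary delirium instruments (the
    long-form Confusion Assessment Method and the 3-Minute Diagnostic
    Interview for CAM) scored concurrently and repeatedly by multiple
    raters.  Fits Bernoulli-logit generalized linear mixed models with
    patient, rater, and patient-by-method random effects by Laplace or
    adaptive Gauss-Hermite approximate maximum likelihood, and derives
    latent-variable summaries feeding repeated-measures Bland-Altman
    analyses, probability ratios, interrater intraclass correlations,
    and Cohen kappa with bootstrap confidence intervals.  Includes a
    synthetic cohort generator with the study's repeated-measures
    structure for testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
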