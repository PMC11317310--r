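Package: amioscore
Title: Subgroup Identification for Differential Amiodarone Response in
    Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates individualized treatment effects of amiodarone for
    out-of-hospital cardiac arrest patients with a shockable rhythm at
    hospital arrival. Implements propensity-score weighting with
    lasso-penalized logistic regression, a linear personalized benefit
    score fitted by minimizing the propensity-weighted logistic likelihood
    loss with modified covariates, leakage-free nested cross-validation
    for score assignment, and inference on the treatment-by-subgroup
    interaction via nonparametric bootstrap confidence intervals and a
    one-sided permutation test in which every model-fitting stage is
    re-run from scratch. Includes a synthetic registry-like cohort
    generator with known ground-truth benefit structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
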