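Package: brlearn
Title: Bayesian Rule Learning for Clinical Biomarker Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns interpretable probabilistic IF-THEN classification rules
    from case/control tables of clinical biomarkers. Implements a Bayesian
    rule learner with both a global greedy parent-set search and a
    decision-tree local-structure search scored by a Dirichlet marginal
    likelihood, supervised Bayesian discretization of continuous predictors
    with a prior penalty on the number of cut-points, per-rule evidence
    statistics (coverage, Laplace posterior probability, one-sided Fisher
    exact p-value), stratified cross-validation with accuracy and AUC, and
    a synthetic cohort generator that emulates a pediatric cardiomyopathy
    cMRI biomarker dataset for end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
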