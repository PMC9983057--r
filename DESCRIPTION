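Package: ipsisurv
Title: Incremental Propensity Score Interventions for Causal Survival
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of cumulative survival probabilities under
    stochastic treatment interventions whose assignment distribution
    depends on the observed treatment process, in particular
    multiplicative-shift and odds-shift incremental propensity score
    interventions for longitudinal data with informative censoring.
    Implements the generalized g-formula, the efficient influence
    function recursion for interventions in canonical form, and four
    estimators: iterated conditional expectation (ICE), inverse
    probability weighting (IPW), multiply robust weighted ICE via
    fractional logistic regression, and targeted maximum likelihood
    estimation with sample splitting and cross-fitting.  Includes two
    built-in longitudinal data-generating processes, exact g-formula
    enumeration for discrete laws, Monte-Carlo computation of
    intervention-world truths, cross-validated learner stacking, and
    nonparametric bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    splines,
    pracma,
    nnet,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
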