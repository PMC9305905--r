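Package: ancred
Title: Reverse-Bayes Analysis of Credibility for Evidence Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse-Bayes tools for assessing the credibility of study findings
    reported as effect estimates with standard errors, confidence intervals, or
    two-by-two event counts. Implements the Analysis of Credibility (AnCred):
    sufficiently sceptical priors and scepticism limits for significant findings,
    advocacy priors and advocacy limits for non-significant ones, intrinsic
    credibility and the probability of replicating the effect direction,
    prior-to-data conversion into equivalent hypothetical trials, a fail-safe N
    equivalence, fixed-effect meta-analysis with prior-predictive (Box) conflict
    checks, Bayes-factor analogues with Lambert-W calibration of the sufficiently
    sceptical prior variance, Bayesian borrowing with two-component normal mixture
    priors, and Reverse-Bayes bounds on the false positive risk from p-value
    calibrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pracma,
    optparse
Config/testthat/edition: 3
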