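#' Reverse-Bayes prior odds from posterior odds
#'
#' The discrete device of imaginary results: fixing the posterior odds of the
#' alternative against the null and dividing out the likelihood ratio of the
#' (possibly imaginary) data recovers the prior odds an observer must hold.
#'
#' @param posterior_odds positive posterior odds `Pr(H1|data)/Pr(H0|data)`.
#' @param likelihood_ratio positive likelihood ratio
#'   `Pr(data|H1)/Pr(data|H0)`.
#' @return prior odds `Pr(H1)/Pr(H0)`.
#' @examples
#' reverse_prior_odds(1, 10^20)  # 1e-20: the ESP thought experiment
#' @export
reverse_prior_odds <- function(posterior_odds, likelihood_ratio) {
  stopifnot(all(posterior_odds > 0), all(likelihood_ratio > 0))
  posterior_odds / likelihood_ratio
}

#' Minimum Bayes factor from a two-sided p-value
#'
#' Four calibrations turning an observed two-sided p-value into a bound on the
#' Bayes factor for the point null (the "p-equals" reading: the Bayes factor
#' is evaluated at the observed p, not at "p or smaller"):
#' \describe{
#'   \item{`local_z`}{mean-zero normal (local) alternatives,
#'     `|z| exp(-z^2/2) sqrt(e)` for `|z| > 1` (see [min_bf01_local()]).}
#'   \item{`simple_z`}{simple alternatives for the two-sided z-test with the
#'     direction of the effect taken into account, `2 exp(-z^2/2)` capped at
#'     1.}
#'   \item{`eplogp`}{`-e p log p` for `p < 1/e`, else 1; a bound under all
#'     unimodal symmetric local priors.}
#'   \item{`eqlogq`}{`-e q log q` with `q = 1 - p` for `p < 1 - 1/e`, else 1;
#'     more conservative, approximately `e p` for small p.}
#' }
#' Throughout, `z = qnorm(1 - p/2)`.
#'
#' @param p two-sided p-value(s) in (0, 1).
#' @param calibration one of `"local_z"`, `"simple_z"`, `"eplogp"`,
#'   `"eqlogq"`.
#' @return minimum Bayes factor(s) in (0, 1].
#' @examples
#' minbf_from_p(0.005, "local_z")
#' minbf_from_p(0.05, "eplogp")  # ~ 0.41
#' @export
minbf_from_p <- function(p, calibration = c("local_z", "simple_z", "eplogp",
                                            "eqlogq")) {
  calibration <- match.arg(calibration)
  stopifnot(all(p > 0), all(p < 1))
  z <- qnorm(1 - p / 2)
  switch(calibration,
         local_z = min_bf01_local(z),
         simple_z = pmin(1, 2 * exp(-z^2 / 2)),
         eplogp = ifelse(p < exp(-1), -exp(1) * p * log(p), 1),
         eqlogq = ifelse(p < 1 - exp(-1),
                         -exp(1) * (1 - p) * log(1 - p), 1))
}

#' False positive risk from a prior probability and a Bayes factor
#'
#' Forward direction of the FPR calculus: the posterior probability that the
#' point null is true given the observed evidence, from
#' `FPR/(1-FPR) = BF01 * Pr(H0)/Pr(H1)`.
#'
#' @param pr_h0 prior probability of the null, strictly inside (0, 1).
#' @param bf01 positive Bayes factor for the null.
#' @return the false positive risk.
#' @examples
#' fpr_from_prior(0.5, 1)  # equipoise and uninformative evidence: 0.5
#' @export
fpr_from_prior <- function(pr_h0, bf01) {
  stopifnot(all(pr_h0 > 0), all(pr_h0 < 1), all(bf01 > 0))
  odds <- bf01 * pr_h0 / (1 - pr_h0)
  odds / (1 + odds)
}

#' Upper bound on the prior null probability for a target false positive risk
#'
#' Reverse direction: given an observed p-value and a target FPR, the largest
#' prior probability of the null compatible with that FPR when the Bayes
#' factor is bounded below by the chosen calibration:
#' `Pr(H0) <= [1 + ((1-FPR)/FPR) * minBF(p)]^{-1}`.
#'
#' @param fpr target false positive risk in (0, 1).
#' @param p observed two-sided p-value(s).
#' @param calibration as in [minbf_from_p()].
#' @return the upper bound(s) on `Pr(H0)`.
#' @examples
#' prior_for_fpr(0.05, 0.005, "local_z")   # ~ 0.37
#' prior_for_fpr(0.05, 0.005, "simple_z")  # ~ 0.57
#' @export
prior_for_fpr <- function(fpr, p, calibration = c("local_z", "simple_z",
                                                  "eplogp", "eqlogq")) {
  stopifnot(all(fpr > 0), all(fpr < 1))
  mb <- minbf_from_p(p, calibration)
  1 / (1 + (1 - fpr) / fpr * mb)
}

#' Prior assumptions needed for the false positive risk to equal the p-value
#'
#' The widespread misreading of a p-value as the probability of the null holds
#' only under strong prior scepticism about the alternative being false:
#' setting `FPR = p` in [prior_for_fpr()] gives the required upper bound on
#' `Pr(H0)`.  For the `eplogp` calibration this is
#' `1 / (1 - e (1-p) log p)`; for `eqlogq` it is approximately
#' `1 / (1 + e (1-p))`, i.e. `1/(1+e) = 26.9%` for small p.
#'
#' @param p two-sided p-value(s).
#' @param calibration as in [minbf_from_p()].
#' @return the upper bound(s) on `Pr(H0)`.
#' @examples
#' prior_for_fpr_equals_p(1e-4, "eqlogq")  # ~ 0.269
#' @export
prior_for_fpr_equals_p <- function(p, calibration = c("local_z", "simple_z",
                                                      "eplogp", "eqlogq")) {
  prior_for_fpr(p, p, calibration)
}
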