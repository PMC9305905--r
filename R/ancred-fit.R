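#' Sufficiently sceptical prior for a significant finding
#'
#' Derives the mean-zero normal prior whose posterior, after updating with the
#' observed estimate, is just non-credible at level `alpha` (the posterior
#' equal-tailed interval touches no effect).  The prior is parameterised by its
#' relative variance `g = tau^2 / sigma^2`,
#' \deqn{g = 1 / (z^2 / z_{\alpha/2}^2 - 1),}
#' defined only while the finding is significant at `alpha` (`z^2 >
#' z_{\alpha/2}^2`).  The scepticism limit `SL` is the `1 - alpha/2` quantile
#' magnitude of this prior; in terms of the level `1 - alpha` confidence limits
#' L and U it equals `(U - L)^2 / (4 sqrt(|U L|))`, identically
#' `z_{alpha/2} sqrt(g) sigma`.  `SL` is reported as a positive magnitude
#' regardless of the sign of the estimate (the prior interval is +-SL).
#'
#' @param est an [effect_estimate()] (or numeric estimate with `se`).
#' @param se standard error when `est` is numeric.
#' @param alpha significance/credibility level (default 0.05).
#' @return Object of class `"sceptical_prior"`: list with `g`, `tau2`, `SL`,
#'   `level = 1 - alpha`, plus the inputs.
#' @examples
#' rec <- logodds_from_counts(95, 229, 283, 400)
#' sceptical_prior(rec)  # g = 0.39, SL = 0.178
#' @export
sceptical_prior <- function(est, se = NULL, alpha = 0.05) {
  est <- as_effect_estimate(est, se)
  check_alpha(alpha)
  z <- est$estimate / est$se
  za <- qnorm(1 - alpha / 2)
  if (z^2 <= za^2)
    stop("sufficiently sceptical prior undefined: the finding is not ",
         "significant at level alpha = ", alpha, call. = FALSE)
  g <- 1 / (z^2 / za^2 - 1)
  tau2 <- g * est$se^2
  structure(list(g = g, tau2 = tau2, SL = za * sqrt(tau2),
                 level = 1 - alpha, alpha = alpha, estimate = est),
            class = "sceptical_prior")
}

#' @export
print.sceptical_prior <- function(x, digits = 3, ...) {
  cat("Sufficiently sceptical prior (mean 0)\n")
  cat(sprintf("  relative variance g = %s, tau^2 = %s\n",
              signif(x$g, digits), signif(x$tau2, digits)))
  cat(sprintf("  scepticism limit SL = %s (prior %g%% interval +-SL)\n",
              signif(x$SL, digits), 100 * x$level))
  invisible(x)
}

#' Advocacy prior for a non-significant finding
#'
#' Derives the normal prior that renders a non-significant finding just
#' credible at level `alpha`: the posterior equal-tailed interval touches no
#' effect from the other side.  Its relative mean is
#' \deqn{f = \mu / \hat\theta = 2 / (1 - z^2 / z_{\alpha/2}^2),}
#' defined only while `z^2 < z_{\alpha/2}^2`.  The prior quantile toward the
#' null is exactly 0, its coefficient of variation is fixed at
#' `tau/|mu| = 1/z_{alpha/2}`, and the advocacy limit `AL = 2 mu` (the prior
#' quantile away from the null) carries the sign of the estimate.
#'
#' @inheritParams sceptical_prior
#' @return Object of class `"advocacy_prior"`: list with `f`, `mu`, `tau`,
#'   `AL`, `cv`, `level`, plus the inputs.
#' @examples
#' rem <- logodds_from_counts(26, 79, 29, 63)
#' advocacy_prior(rem)  # AL = -1.89
#' @export
advocacy_prior <- function(est, se = NULL, alpha = 0.05) {
  est <- as_effect_estimate(est, se)
  check_alpha(alpha)
  z <- est$estimate / est$se
  za <- qnorm(1 - alpha / 2)
  if (z^2 >= za^2)
    stop("advocacy prior undefined: the finding is significant at level ",
         "alpha = ", alpha, call. = FALSE)
  f <- 2 / (1 - z^2 / za^2)
  mu <- f * est$estimate
  tau <- abs(mu) / za
  structure(list(f = f, mu = mu, tau = tau, AL = 2 * mu, cv = 1 / za,
                 level = 1 - alpha, alpha = alpha, estimate = est),
            class = "advocacy_prior")
}

#' @export
print.advocacy_prior <- function(x, digits = 3, ...) {
  cat("Advocacy prior\n")
  cat(sprintf("  mean mu = %s (relative mean f = %s), sd tau = %s (CV = %s)\n",
              signif(x$mu, digits), signif(x$f, digits),
              signif(x$tau, digits), signif(x$cv, digits)))
  cat(sprintf("  advocacy limit AL = %s (prior %g%% interval from 0 to AL)\n",
              signif(x$AL, digits), 100 * x$level))
  invisible(x)
}

#' Intrinsic credibility of an unprecedented finding
#'
#' A finding is intrinsically credible when it withstands the sceptical prior
#' extracted from itself.  The level-free summary is the p-value for intrinsic
#' credibility
#' \deqn{p_{IC} = 2 (1 - \Phi(|z| / \sqrt{2})),}
#' the ordinary p-value computed with doubled variance.  Linked to it is the
#' probability `p_rep = 1 - p_IC / 2` that a replication yields an estimate in
#' the same direction.  The credibility ratio (larger CI limit over smaller,
#' when both share a sign) offers a quick check: a significant finding is
#' intrinsically credible at its own level when the ratio is below 5.8.
#'
#' @inheritParams sceptical_prior
#' @return Object of class `"intrinsic_credibility"`: list with `p_ic`,
#'   `p_rep`, `credibility_ratio` (NA when the interval spans 0),
#'   `intrinsically_credible` (`p_ic <= alpha`), `z` and `alpha`.
#' @examples
#' intrinsic_credibility(logodds_from_counts(95, 229, 283, 400))
#' @export
intrinsic_credibility <- function(est, se = NULL, alpha = 0.05) {
  est <- as_effect_estimate(est, se)
  check_alpha(alpha)
  z <- est$estimate / est$se
  p_ic <- 2 * pnorm(abs(z) / sqrt(2), lower.tail = FALSE)
  ci <- ci_from_estimate(est, level = 1 - alpha)
  ratio <- if (ci$lower * ci$upper > 0)
    max(abs(ci$lower), abs(ci$upper)) / min(abs(ci$lower), abs(ci$upper))
  else NA_real_
  structure(list(p_ic = p_ic, p_rep = 1 - p_ic / 2,
                 credibility_ratio = ratio,
                 intrinsically_credible = p_ic <= alpha,
                 z = z, alpha = alpha),
            class = "intrinsic_credibility")
}

#' @export
print.intrinsic_credibility <- function(x, digits = 3, ...) {
  cat(sprintf("Intrinsic credibility: p_IC = %s, p_rep = %s\n",
              signif(x$p_ic, digits), signif(x$p_rep, digits)))
  if (!is.na(x$credibility_ratio))
    cat(sprintf("  credibility ratio = %s (%s 5.8)\n",
                signif(x$credibility_ratio, digits),
                if (x$credibility_ratio < 5.8) "<" else ">="))
  cat(sprintf("  intrinsically credible at alpha = %g: %s\n", x$alpha,
              x$intrinsically_credible))
  invisible(x)
}

#' Credibility ratio of a confidence interval
#'
#' Ratio of the larger to the smaller interval limit in magnitude, defined only
#' when both limits share a sign.  Results with a ratio strictly below 5.8 are
#' intrinsically credible at the interval's own level.
#'
#' @param lower,upper interval limits, or a `"conf_int"` object as `lower`.
#' @return list with `ratio` and logical `intrinsically_credible`.
#' @examples
#' credibility_ratio(-0.82, -0.25)  # 3.27 < 5.8
#' @export
credibility_ratio <- function(lower, upper = NULL) {
  if (inherits(lower, "conf_int")) {
    upper <- lower$upper
    lower <- lower$lower
  }
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  if (lower * upper <= 0)
    stop("credibility ratio undefined: interval includes no effect",
         call. = FALSE)
  ratio <- max(abs(lower), abs(upper)) / min(abs(lower), abs(upper))
  list(ratio = ratio, intrinsically_credible = ratio < 5.8)
}

#' p-value thresholds for intrinsic credibility
#'
#' Two analytic thresholds at level `alpha`.  Under the prior-based
#' self-challenge (estimate outside its own sceptical prior interval,
#' `theta^2 > SL^2`) the boundary z solves `z^2 = z_{alpha/2}^2 (1+sqrt(5))/2`,
#' giving p = 0.013 at alpha = 0.05.  Under the prior-predictive (Box) check
#' the boundary is `z = sqrt(2) z_{alpha/2}`, giving p = 0.0056 at alpha =
#' 0.05 — a principled argument for the proposed 0.005 significance threshold.
#'
#' @param alpha level in (0, 1).
#' @return list with `p_matthews` (prior-based) and `p_box` (prior-predictive).
#' @examples
#' intrinsic_p_thresholds(0.05)
#' @export
intrinsic_p_thresholds <- function(alpha = 0.05) {
  check_alpha(alpha)
  za <- qnorm(1 - alpha / 2)
  golden <- (1 + sqrt(5)) / 2
  list(p_matthews = 2 * pnorm(za * sqrt(golden), lower.tail = FALSE),
       p_box = 2 * pnorm(sqrt(2) * za, lower.tail = FALSE))
}

#' Fail-safe N via the sceptical prior
#'
#' Number of unpublished null studies required to render a pooled meta-analytic
#' estimate non-significant at level `alpha`, assuming the unseen studies have
#' zero effect and the average precision `delta' / n` of the published ones.
#' The Reverse-Bayes closed form is `N = n / (delta' * tau^2)` with
#' `tau^2 = g * sigma^2` the sufficiently sceptical prior variance of the
#' pooled estimate.  A brute-force count (smallest number of added zero-effect
#' studies pushing `|z|` below `z_{alpha/2}`) is reported alongside; its value
#' equals `ceiling(N)`.
#'
#' @param pooled pooled [effect_estimate()] (or numeric estimate with `se`).
#' @param n_studies number of studies behind the pooled estimate.
#' @param total_precision pooled posterior precision `delta'`.
#' @param se standard error when `pooled` is numeric.
#' @param alpha significance level.
#' @return Object of class `"failsafe"`: list with `n_failsafe` (closed form),
#'   `n_failsafe_int = ceiling(n_failsafe)`, `n_iterative` (brute-force count),
#'   `g` and `tau2`.
#' @examples
#' failsafe_n(effect_estimate(-0.42, 0.11), n_studies = 7,
#'            total_precision = 83.8)
#' @export
failsafe_n <- function(pooled, n_studies, total_precision, se = NULL,
                       alpha = 0.05) {
  pooled <- as_effect_estimate(pooled, se)
  stopifnot(n_studies >= 1, total_precision > 0)
  sp <- sceptical_prior(pooled, alpha = alpha)  # errors if non-significant
  n_fs <- n_studies / (total_precision * sp$tau2)
  structure(list(n_failsafe = n_fs, n_failsafe_int = ceiling(n_fs),
                 n_iterative = failsafe_iterative(pooled$estimate,
                                                  total_precision, n_studies,
                                                  alpha),
                 g = sp$g, tau2 = sp$tau2, alpha = alpha),
            class = "failsafe")
}

# brute-force augmentation: add k zero-effect studies at the average precision
# delta'/n until the pooled result loses significance
failsafe_iterative <- function(mu, delta, n, alpha, kmax = 1e6) {
  za <- qnorm(1 - alpha / 2)
  avg <- delta / n
  for (k in 0:kmax) {
    z <- mu * delta / sqrt(delta + k * avg)
    if (abs(z) <= za) return(k)
  }
  stop("fail-safe N exceeds ", kmax, call. = FALSE)
}

#' @export
print.failsafe <- function(x, digits = 3, ...) {
  cat(sprintf("Fail-safe N: %s (ceiling %d; iterative count %d)\n",
              signif(x$n_failsafe, digits), x$n_failsafe_int, x$n_iterative))
  cat(sprintf("  sceptical g = %s, tau^2 = %s at alpha = %g\n",
              signif(x$g, digits), signif(x$tau2, digits), x$alpha))
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("'alpha' must be a probability strictly between 0 and 1",
         call. = FALSE)
  invisible(alpha)
}
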