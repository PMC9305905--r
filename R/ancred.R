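#' Analysis of Credibility for a single finding
#'
#' The central Reverse-Bayes fit.  Given an effect estimate with standard
#' error (or a two-by-two table, or a confidence interval), `ancred()` decides
#' whether the finding is significant at `alpha` and derives the matching
#' challenge prior: the mean-zero [sceptical_prior()] that would make a
#' significant finding just non-credible, or the [advocacy_prior()] that would
#' make a non-significant finding just credible.  Intrinsic credibility is
#' assessed alongside, and when an event rate is available the challenge prior
#' is converted into an equivalent hypothetical trial.
#'
#' @param x an [effect_estimate()], a numeric estimate (then give `se`), or a
#'   two-by-two count table created with [logodds_from_counts()].
#' @param se standard error when `x` is numeric.
#' @param alpha credibility level (default 0.05).
#' @param rate event rate used for the prior-to-data conversion (overall rate
#'   for sceptical priors, control-arm rate for advocacy priors); optional.
#' @param label optional study label.
#' @return Object of class `"ancred"`: list with elements `estimate`, `z`,
#'   `p`, `ci`, `mode` (`"sceptical"` or `"advocacy"`), `prior` (the challenge
#'   prior object), `intrinsic` ([intrinsic_credibility()]), `equivalent` (an
#'   equivalent-study object or NULL) and `alpha`.  Methods: `print`,
#'   `summary`, `coef`, `confint`, `plot`.
#' @examples
#' rec <- ancred(logodds_from_counts(95, 229, 283, 400), rate = 378 / 1007)
#' rec
#' coef(rec)
#' @export
ancred <- function(x, se = NULL, alpha = 0.05, rate = NULL, label = NULL) {
  est <- as_effect_estimate(x, se)
  if (!is.null(label)) est$label <- label
  check_alpha(alpha)
  ts <- test_statistics(est)
  za <- qnorm(1 - alpha / 2)
  if (ts$z^2 == za^2)
    stop("the finding sits exactly at the significance boundary; ",
         "both Reverse-Bayes priors are undefined there", call. = FALSE)
  mode <- if (ts$z^2 > za^2) "sceptical" else "advocacy"
  prior <- if (mode == "sceptical") sceptical_prior(est, alpha = alpha)
           else advocacy_prior(est, alpha = alpha)
  equivalent <- if (!is.null(rate)) {
    if (mode == "sceptical") sceptical_equivalent(prior$tau2, rate)
    else advocacy_equivalent(prior$AL, rate, alpha = alpha)
  }
  structure(list(estimate = est, z = ts$z, p = ts$p,
                 ci = ci_from_estimate(est, level = 1 - alpha),
                 mode = mode, prior = prior,
                 intrinsic = intrinsic_credibility(est, alpha = alpha),
                 equivalent = equivalent, alpha = alpha),
            class = "ancred")
}

#' @export
print.ancred <- function(x, digits = 3, ...) {
  lab <- if (!is.null(x$estimate$label)) paste0(": ", x$estimate$label) else ""
  cat(sprintf("Analysis of Credibility%s\n", lab))
  cat(sprintf("  estimate %s (se %s), z = %s, p = %s -> %s at alpha = %g\n",
              signif(x$estimate$estimate, digits), signif(x$estimate$se, digits),
              signif(x$z, digits), signif(x$p, digits),
              if (x$mode == "sceptical") "significant" else "non-significant",
              x$alpha))
  print(x$prior, digits = digits)
  invisible(x)
}

#' @export
summary.ancred <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  print(object$intrinsic, digits = digits)
  if (!is.null(object$equivalent)) print(object$equivalent, digits = digits)
  invisible(object)
}

#' @export
coef.ancred <- function(object, ...) {
  if (object$mode == "sceptical")
    c(g = object$prior$g, tau2 = object$prior$tau2, SL = object$prior$SL)
  else
    c(f = object$prior$f, mu = object$prior$mu, tau = object$prior$tau,
      AL = object$prior$AL, cv = object$prior$cv)
}

#' @export
confint.ancred <- function(object, parm, level, ...) {
  out <- with(object$ci, c(lower, upper))
  names(out) <- paste0(100 * c((1 - object$ci$level) / 2,
                               1 - (1 - object$ci$level) / 2), "%")
  out
}

#' Plot an Analysis of Credibility
#'
#' Draws the data interval, the challenge prior interval, and the fixed
#' boundary posterior on one axis, mirroring the usual AnCred display.
#'
#' @param x an `"ancred"` object.
#' @param ... further arguments passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ancred <- function(x, ...) {
  est <- x$estimate
  za <- qnorm(1 - x$alpha / 2)
  # boundary posterior implied by prior + data (null-side limit at 0)
  prior_nb <- if (x$mode == "sceptical") normal_belief(0, 1 / x$prior$tau2)
              else normal_belief(x$prior$mu, 1 / x$prior$tau^2)
  post <- forward_update(prior_nb, est)
  psd <- 1 / sqrt(post$precision)
  ints <- rbind(data  = c(x$ci$lower, est$estimate, x$ci$upper),
                prior = if (x$mode == "sceptical")
                          c(-x$prior$SL, 0, x$prior$SL)
                        else sort(c(0, x$prior$mu, x$prior$AL)),
                posterior = c(post$mean - za * psd, post$mean,
                              post$mean + za * psd))
  graphics::plot(NA, xlim = range(ints, 0), ylim = c(0.5, 3.5), yaxt = "n",
                 xlab = "effect (log-OR scale)", ylab = "", ...)
  graphics::axis(2, at = 3:1, labels = rownames(ints), las = 1)
  graphics::abline(v = 0, lty = 2, col = "grey")
  for (i in 1:3) {
    graphics::segments(ints[i, 1], 4 - i, ints[i, 3], 4 - i)
    graphics::points(ints[i, 2], 4 - i, pch = 19)
  }
  invisible(x)
}
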