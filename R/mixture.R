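#' Two-or-more component normal mixture distribution
#'
#' Used as prior or posterior in Bayesian borrowing: a weak (unit-information)
#' component stabilises the analysis while an informative component carries
#' external data.  On the log-OR scale the unit-information variance is 4.
#'
#' @param weights non-negative weights; normalised to sum to 1.
#' @param means component means.
#' @param variances strictly positive component variances.
#' @return Object of class `"normal_mixture"`.
#' @examples
#' normal_mixture(c(0.5, 0.5), c(0, -0.53), c(4, 0.0209))
#' @export
normal_mixture <- function(weights, means, variances) {
  stopifnot(length(weights) == length(means),
            length(means) == length(variances),
            all(weights >= 0), sum(weights) > 0, all(variances > 0))
  structure(list(weights = weights / sum(weights), means = means,
                 variances = variances),
            class = "normal_mixture")
}

#' @export
print.normal_mixture <- function(x, digits = 3, ...) {
  cat(sprintf("Normal mixture (%d components)\n", length(x$weights)))
  for (k in seq_along(x$weights))
    cat(sprintf("  %s * N(%s, %s)\n", signif(x$weights[k], digits),
                signif(x$means[k], digits), signif(x$variances[k], digits)))
  invisible(x)
}

#' Posterior of a normal mixture prior under a normal likelihood
#'
#' Each component is updated conjugately; the posterior weights are the prior
#' weights multiplied by the marginal likelihood of the data under each
#' component, `N(x; m_k, sigma^2 + v_k)`, renormalised.
#'
#' @param prior a [normal_mixture()].
#' @param data an [effect_estimate()].
#' @return A [normal_mixture()] (the posterior).
#' @export
mixture_posterior <- function(prior, data) {
  stopifnot(inherits(prior, "normal_mixture"),
            inherits(data, "effect_estimate"))
  s2 <- data$se^2
  marg <- prior$weights *
    dnorm(data$estimate, prior$means, sqrt(s2 + prior$variances))
  post_prec <- 1 / prior$variances + 1 / s2
  post_mean <- (prior$means / prior$variances + data$estimate / s2) / post_prec
  normal_mixture(marg, post_mean, 1 / post_prec)
}

#' Distribution function of a normal mixture
#'
#' @param mix a [normal_mixture()].
#' @param q vector of quantiles.
#' @return `P(X <= q)` for each element of `q`.
#' @export
mixture_cdf <- function(mix, q) {
  stopifnot(inherits(mix, "normal_mixture"))
  vapply(q, function(x)
    sum(mix$weights * pnorm(x, mix$means, sqrt(mix$variances))), 0.0)
}

#' Quantile of a normal mixture
#'
#' There is no closed form for mixture quantiles; the CDF is inverted by
#' bracketed root finding to an absolute tolerance of 1e-10, with the bracket
#' grown geometrically from the component-wise normal quantile envelope if
#' needed.
#'
#' @param mix a [normal_mixture()].
#' @param prob probability in (0, 1); vectorised.
#' @return the quantile(s) `x` with `mixture_cdf(mix, x) = prob`.
#' @export
mixture_quantile <- function(mix, prob) {
  stopifnot(inherits(mix, "normal_mixture"), all(prob > 0), all(prob < 1))
  vapply(prob, function(p) {
    # envelope: mixture quantile lies within the extreme component quantiles
    lo <- min(qnorm(p, mix$means, sqrt(mix$variances)))
    hi <- max(qnorm(p, mix$means, sqrt(mix$variances)))
    if (lo == hi) return(lo)
    f <- function(x) mixture_cdf(mix, x) - p
    width <- hi - lo
    tries <- 0
    while (f(lo) > 0 || f(hi) < 0) {  # defensive; envelope should bracket
      lo <- lo - width; hi <- hi + width; width <- 2 * width
      tries <- tries + 1
      if (tries > 60) stop("failed to bracket mixture quantile", call. = FALSE)
    }
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, 0.0)
}

#' Reverse-Bayes mixing weight for Bayesian borrowing
#'
#' How much prior weight must an informative component (for instance the
#' posterior of an earlier trial) receive, against a weak unit-information
#' component, for a non-significant finding to become credible?  The function
#' root-solves for the smallest weight `w` on the informative component such
#' that the equal-tailed `1 - alpha` posterior credible interval just excludes
#' no effect (null-side limit exactly 0).
#'
#' The exposed weight is the one on the *informative* component — the level of
#' prior belief advocates must justify.  Monotonicity of the null-side limit
#' in `w` is checked on a grid first; if it fails, all crossings are located
#' and the smallest is returned (with a warning).
#'
#' @param data an [effect_estimate()] for the finding under assessment.
#' @param informative `c(mean, variance)` of the informative component.
#' @param weak `c(mean, variance)` of the weak component; default the
#'   unit-information log-OR prior `c(0, 4)`.
#' @param alpha credibility level.
#' @param grid_n grid size for the monotonicity check.
#' @return list with `weight` (NA when unachievable), `achievable`,
#'   `null_side` (`"upper"` or `"lower"`), and `limit_at_weight`.
#' @examples
#' rec <- logodds_from_counts(95, 229, 283, 400)
#' rem <- logodds_from_counts(26, 79, 29, 63)
#' reverse_bayes_weight(rem, informative = c(rec$estimate, rec$se^2))
#' @export
reverse_bayes_weight <- function(data, informative, weak = c(0, 4),
                                 alpha = 0.05, grid_n = 101) {
  stopifnot(inherits(data, "effect_estimate"),
            length(informative) == 2L, informative[2] > 0,
            length(weak) == 2L, weak[2] > 0)
  check_alpha(alpha)

  post_at <- function(w) {
    mixture_posterior(normal_mixture(c(1 - w, w), c(weak[1], informative[1]),
                                     c(weak[2], informative[2])), data)
  }
  # the null-side limit is the posterior quantile nearest zero; its side is
  # set by the direction the informative prior pulls the posterior
  full <- post_at(1)
  pull_neg <- sum(full$weights * full$means) < 0
  side_prob <- if (pull_neg) 1 - alpha / 2 else alpha / 2
  limit <- function(w) mixture_quantile(post_at(w), side_prob)
  # credible when the null-side limit has crossed 0 toward the effect side
  gap <- function(w) if (pull_neg) limit(w) else -limit(w)  # credible: gap <= 0

  ws <- seq(0, 1, length.out = grid_n)
  gaps <- vapply(ws, gap, 0.0)
  out <- list(weight = NA_real_, achievable = FALSE,
              null_side = if (pull_neg) "upper" else "lower",
              limit_at_weight = NA_real_)
  if (all(gaps > 0)) return(out)          # not achievable for any w in [0,1]
  if (gaps[1] <= 0) {                     # already credible without borrowing
    out$weight <- 0
    out$achievable <- TRUE
    out$limit_at_weight <- limit(0)
    return(out)
  }
  sign_changes <- which(gaps[-1] <= 0 & gaps[-grid_n] > 0)
  if (length(sign_changes) > 1L)
    warning("posterior null-side limit is not monotone in the weight; ",
            "returning the smallest crossing")
  i <- sign_changes[1L]
  root <- uniroot(gap, c(ws[i], ws[i + 1L]), tol = 1e-9)$root
  out$weight <- root
  out$achievable <- TRUE
  out$limit_at_weight <- limit(root)
  out
}
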