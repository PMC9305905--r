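#' Effect estimate with standard error
#'
#' Container for a point estimate and its standard error on a scale where the
#' estimate is approximately normally distributed (for comparative binary
#' outcomes, the log odds ratio).  All Reverse-Bayes machinery in the package
#' consumes these objects.
#'
#' @param estimate numeric point estimate (log-OR scale for binary outcomes).
#' @param se positive standard error of the estimate.
#' @param label optional study label, carried along for printing.
#' @return An object of class `"effect_estimate"`: a list with elements
#'   `estimate`, `se` and (optionally) `label`.
#' @examples
#' effect_estimate(-0.42, 0.11)
#' @export
effect_estimate <- function(estimate, se, label = NULL) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L, is.finite(estimate),
            is.numeric(se), length(se) == 1L, is.finite(se))
  if (se <= 0) stop("'se' must be strictly positive", call. = FALSE)
  structure(list(estimate = estimate, se = se, label = label),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  lab <- if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  ts <- test_statistics(x)
  cat(sprintf("Effect estimate%s: %s (se %s), z = %s, p = %s\n", lab,
              signif(x$estimate, digits), signif(x$se, digits),
              signif(ts$z, digits), signif(ts$p, digits)))
  invisible(x)
}

# coerce numeric input (estimate, se) or pass through an effect_estimate
as_effect_estimate <- function(x, se = NULL) {
  if (inherits(x, "effect_estimate")) return(x)
  effect_estimate(x, se)
}

#' Log odds ratio from a two-by-two table
#'
#' Computes the maximum-likelihood log odds ratio and its Woolf standard error
#' `sqrt(1/m1 + 1/n1 + 1/m2 + 1/n2)` from arm-level events and non-events.
#' Zero cells are an error: the log odds ratio is undefined there and no
#' continuity correction is applied.
#'
#' @param events_t,nonevents_t events and non-events in the treatment arm.
#' @param events_c,nonevents_c events and non-events in the control arm.
#' @param label optional study label.
#' @return An [effect_estimate()] on the log-OR scale.
#' @examples
#' # RECOVERY trial: 95/324 deaths under dexamethasone vs 283/683 usual care
#' logodds_from_counts(95, 324 - 95, 283, 683 - 283)
#' @export
logodds_from_counts <- function(events_t, nonevents_t, events_c, nonevents_c,
                                label = NULL) {
  cells <- c(events_t = events_t, nonevents_t = nonevents_t,
             events_c = events_c, nonevents_c = nonevents_c)
  stopifnot(all(is.finite(cells)), all(cells >= 0))
  if (any(cells == 0)) {
    bad <- names(cells)[cells == 0][1L]
    stop("log odds ratio undefined: cell '", bad, "' is zero", call. = FALSE)
  }
  est <- log((events_t / nonevents_t) / (events_c / nonevents_c))
  se <- sqrt(sum(1 / cells))
  effect_estimate(est, se, label = label)
}

#' Invert a Wald confidence interval to an estimate and standard error
#'
#' Assumes the interval is symmetric around a normally distributed point
#' estimate, so `estimate = (L + U)/2` and `se = (U - L) / (2 * z_{alpha/2})`.
#'
#' @param lower,upper interval limits with `lower < upper`.
#' @param level confidence level in (0, 1); default 0.95.
#' @param label optional study label.
#' @return An [effect_estimate()].
#' @examples
#' estimate_from_ci(-0.63, -0.20)  # pooled corticosteroids log-OR
#' @export
estimate_from_ci <- function(lower, upper, level = 0.95, label = NULL) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.finite(lower),
            is.finite(upper))
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("'level' must be a probability strictly between 0 and 1", call. = FALSE)
  if (lower >= upper) stop("'lower' must be smaller than 'upper'", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  effect_estimate((lower + upper) / 2, (upper - lower) / (2 * z), label = label)
}

#' Wald confidence interval for an effect estimate
#'
#' @param est an [effect_estimate()] (or a numeric estimate with `se` given).
#' @param se standard error when `est` is numeric.
#' @param level confidence level in (0, 1).
#' @return An object of class `"conf_int"`: list with `lower`, `upper`, `level`.
#' @examples
#' ci_from_estimate(effect_estimate(-0.53, 0.145))
#' @export
ci_from_estimate <- function(est, se = NULL, level = 0.95) {
  est <- as_effect_estimate(est, se)
  stopifnot(level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(lower = est$estimate - z * est$se,
                 upper = est$estimate + z * est$se,
                 level = level),
            class = "conf_int")
}

#' @export
print.conf_int <- function(x, digits = 4, ...) {
  cat(sprintf("%g%% CI: [%s, %s]\n", 100 * x$level,
              signif(x$lower, digits), signif(x$upper, digits)))
  invisible(x)
}

#' z statistic and two-sided p-value
#'
#' @inheritParams ci_from_estimate
#' @return list with `z = estimate/se` and `p = 2 * (1 - pnorm(|z|))`.
#' @examples
#' test_statistics(effect_estimate(-0.42, 0.11))  # z = -3.81
#' @export
test_statistics <- function(est, se = NULL) {
  est <- as_effect_estimate(est, se)
  z <- est$estimate / est$se
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}
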