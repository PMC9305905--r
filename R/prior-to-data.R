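#' Equivalent hypothetical trial for a sceptical prior (large-study regime)
#'
#' Under equal events `m` per arm and large numbers of non-events, the log-OR
#' variance of a two-arm trial reduces to `2/m`, so a mean-zero prior with
#' variance `tau2` carries the evidence of a trial with `m = 2/tau2` events in
#' both arms.
#'
#' @param tau2 positive prior variance on the log-OR scale.
#' @return An `"equivalent_study"` with `m` set and `n` unset (`NA`).
#' @export
sceptical_equivalent_large <- function(tau2) {
  stopifnot(is.numeric(tau2), tau2 > 0)
  new_equivalent_study(m = 2 / tau2, n = NA_real_, K = 1, R = NA_real_,
                       tau2 = tau2, kind = "sceptical (large-study)")
}

#' Equivalent hypothetical trial for a sceptical prior
#'
#' A mean-zero sceptical prior with variance `tau2` on the log-OR scale is
#' matched by a balanced trial with `m` events and `n` non-events in each arm
#' (variance `2/m + 2/n`), with the event rate `R = m/(m+n)` constrained to
#' that of the study under assessment:
#' `m = 2 / (tau2 (1 - R))`, `n = m (1 - R) / R`.
#'
#' @param tau2 positive prior variance on the log-OR scale.
#' @param rate event rate R in (0, 1) to match.
#' @return An `"equivalent_study"` with unrounded `m`, `n` and their
#'   nearest-integer counterparts.
#' @examples
#' sp <- sceptical_prior(logodds_from_counts(95, 229, 283, 400))
#' sceptical_equivalent(sp$tau2, rate = 378 / 1007)  # m = 389, n = 648
#' @export
sceptical_equivalent <- function(tau2, rate) {
  stopifnot(is.numeric(tau2), tau2 > 0)
  check_rate(rate)
  m <- 2 / (tau2 * (1 - rate))
  n <- m * (1 - rate) / rate
  new_equivalent_study(m = m, n = n, K = 1, R = rate, tau2 = tau2,
                       kind = "sceptical")
}

#' Equivalent hypothetical trial for an advocacy prior
#'
#' An advocacy prior with limit `AL` has mean `mu = AL/2` and variance
#' `tau2 = AL^2 / (4 z_{alpha/2}^2)`.  Its equivalent trial has `m` events in
#' both arms but unequal non-events, the arms being allocated 1:K with
#' `K = exp(AL/2)` so that the imbalance encodes the non-zero prior mean:
#' the reference (null-supporting) arm has `n` non-events and the other arm
#' `n / K`, where
#' `m = (2 - R (1 - K)) / (tau2 (1 - R))` and `n = m (1 - R) / R`
#' with `R` the reference-arm event rate (variance `2/m + (K+1)/n`).
#'
#' @param AL non-zero advocacy limit on the log-OR scale (signed).
#' @param rate reference-arm (e.g. control) event rate in (0, 1).
#' @param alpha level used when deriving the prior (default 0.05).
#' @return An `"equivalent_study"` with `m`, `n`, allocation ratio `K`, and
#'   derived arm totals.
#' @examples
#' ap <- advocacy_prior(logodds_from_counts(26, 79, 29, 63))
#' advocacy_equivalent(ap$AL, rate = 29 / 92)  # m = 11, n = 25, K = 0.39
#' @export
advocacy_equivalent <- function(AL, rate, alpha = 0.05) {
  stopifnot(is.numeric(AL), length(AL) == 1L, is.finite(AL))
  if (AL == 0) stop("advocacy limit must be non-zero", call. = FALSE)
  check_rate(rate)
  check_alpha(alpha)
  za <- qnorm(1 - alpha / 2)
  mu <- AL / 2
  K <- exp(mu)
  tau2 <- AL^2 / (4 * za^2)
  m <- (2 - rate * (1 - K)) / (tau2 * (1 - rate))
  n <- m * (1 - rate) / rate
  new_equivalent_study(m = m, n = n, K = K, R = rate, tau2 = tau2,
                       kind = "advocacy")
}

# internal constructor; rounding is to the nearest integer, which is what the
# reported m/n values use (the exact reals are kept alongside)
new_equivalent_study <- function(m, n, K, R, tau2, kind) {
  structure(list(m = m, n = n, m_int = round(m), n_int = round(n),
                 K = K, R = R, tau2 = tau2, kind = kind,
                 rounded = !isTRUE(all.equal(c(m, n), round(c(m, n))))),
            class = "equivalent_study")
}

#' @export
print.equivalent_study <- function(x, digits = 3, ...) {
  cat(sprintf("Equivalent prior study (%s)\n", x$kind))
  if (is.na(x$n)) {
    cat(sprintf("  m = %s events per arm (large-study regime)\n",
                signif(x$m, digits)))
  } else if (x$kind == "advocacy") {
    ref_total <- x$m_int + x$n_int
    other_total <- round(x$m + x$n / x$K)
    cat(sprintf("  m = %d events per arm; non-events %d vs %d (allocation 1:%s, K = %s)\n",
                x$m_int, x$n_int, round(x$n / x$K), signif(1 / x$K, digits),
                signif(x$K, digits)))
    cat(sprintf("  arm totals: %d (reference) vs %d patients\n",
                ref_total, other_total))
  } else {
    cat(sprintf("  m = %d events and n = %d non-events in both arms (%d patients each)\n",
                x$m_int, x$n_int, x$m_int + x$n_int))
  }
  cat(sprintf("  matched event rate R = %s, prior variance tau^2 = %s\n",
              signif(x$R, digits), signif(x$tau2, digits)))
  invisible(x)
}

#' Reconstruct the prior variance carried by an equivalent study
#'
#' Inverse of the prior-to-data conversion: `2/m + 2/n` for balanced
#' (sceptical) trials, `2/m + (K+1)/n` for 1:K-allocated (advocacy) trials.
#' Useful as a round-trip check, especially after integer rounding.
#'
#' @param eq an `"equivalent_study"`.
#' @param use_integers reconstruct from the rounded counts instead of the
#'   exact reals.
#' @return the implied prior variance.
#' @export
equivalent_study_variance <- function(eq, use_integers = FALSE) {
  stopifnot(inherits(eq, "equivalent_study"))
  m <- if (use_integers) eq$m_int else eq$m
  n <- if (use_integers) eq$n_int else eq$n
  if (is.na(n)) return(2 / m)
  2 / m + (eq$K + 1) / n
}

check_rate <- function(rate) {
  if (!(is.numeric(rate) && length(rate) == 1L && rate > 0 && rate < 1))
    stop("'rate' must be a probability strictly between 0 and 1",
         call. = FALSE)
  invisible(rate)
}
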