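#' Normal belief parameterised by mean and precision
#'
#' Prior and posterior beliefs are stored as (mean, precision) rather than
#' (mean, variance) so the flat initial prior of a fixed-effect meta-analysis
#' is exactly representable as precision zero (the mean is then ignored).
#'
#' @param mean numeric mean.
#' @param precision non-negative precision (1/variance); 0 encodes flatness.
#' @return Object of class `"normal_belief"`.
#' @examples
#' normal_belief(0, 0)        # flat
#' normal_belief(-0.26, 36.1) # leave-one-out meta-analytic prior
#' @export
normal_belief <- function(mean, precision) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(precision), length(precision) == 1L,
            is.finite(precision), precision >= 0)
  if (precision == 0) mean <- 0  # flat prior: the mean carries no information
  stopifnot(is.finite(mean))
  structure(list(mean = mean, precision = precision), class = "normal_belief")
}

#' @export
print.normal_belief <- function(x, digits = 4, ...) {
  if (x$precision == 0) {
    cat("Normal belief: flat (precision 0)\n")
  } else {
    cat(sprintf("Normal belief: mean %s, precision %s (sd %s)\n",
                signif(x$mean, digits), signif(x$precision, digits),
                signif(1 / sqrt(x$precision), digits)))
  }
  invisible(x)
}

#' Conjugate forward update of a normal belief
#'
#' Combines a normal prior (mean `mu`, precision `delta`) with a normally
#' distributed observation `x` of precision `kappa = 1/se^2`:
#' `delta' = delta + kappa`, `mu' = (mu * delta + x * kappa) / delta'`.
#'
#' @param prior a [normal_belief()].
#' @param data an [effect_estimate()].
#' @return The posterior [normal_belief()].
#' @seealso [reverse_update()] for the inverse operation.
#' @export
forward_update <- function(prior, data) {
  stopifnot(inherits(prior, "normal_belief"), inherits(data, "effect_estimate"))
  kappa <- 1 / data$se^2
  dp <- prior$precision + kappa
  mp <- (prior$mean * prior$precision + data$estimate * kappa) / dp
  normal_belief(mp, dp)
}

#' Reverse-Bayes update: remove an observation from a posterior
#'
#' Inverts [forward_update()]: given the posterior and the data, recovers the
#' prior via `delta = delta' - kappa` and `mu = (mu' delta' - x kappa) / delta`.
#' Only defined while the posterior precision exceeds the observational
#' precision.
#'
#' @param posterior a [normal_belief()].
#' @param data an [effect_estimate()].
#' @return The implied prior [normal_belief()].
#' @examples
#' post <- normal_belief(-0.42, 83.8)
#' reverse_update(post, effect_estimate(-0.53, 0.145))  # ~ N(-0.26, 1/36.1)
#' @export
reverse_update <- function(posterior, data) {
  stopifnot(inherits(posterior, "normal_belief"),
            inherits(data, "effect_estimate"))
  kappa <- 1 / data$se^2
  if (posterior$precision <= kappa)
    stop("update not invertible: posterior precision (",
         signif(posterior$precision, 6),
         ") must exceed the observational precision (", signif(kappa, 6), ")",
         call. = FALSE)
  delta <- posterior$precision - kappa
  mu <- (posterior$mean * posterior$precision - data$estimate * kappa) / delta
  normal_belief(mu, delta)
}

# normalise the various study inputs to a list of effect_estimate objects
as_estimate_list <- function(studies, ses = NULL, labels = NULL) {
  if (inherits(studies, "effect_estimate")) studies <- list(studies)
  if (is.data.frame(studies)) return(table_to_estimates(studies))
  if (is.numeric(studies)) {
    stopifnot(!is.null(ses), length(ses) == length(studies))
    if (is.null(labels)) labels <- names(studies)
    return(lapply(seq_along(studies), function(i)
      effect_estimate(studies[i], ses[i], label = labels[i])))
  }
  stopifnot(is.list(studies),
            all(vapply(studies, inherits, TRUE, "effect_estimate")))
  studies
}

#' Fixed-effect meta-analysis by iterated conjugate updating
#'
#' Pools normally distributed study estimates by starting from a flat prior
#' (precision zero) and applying [forward_update()] study by study, which is
#' identical to classical inverse-variance pooling: the pooled precision is
#' the sum of the study precisions and the pooled mean their precision-weighted
#' average.
#'
#' @param studies a list of [effect_estimate()] objects, a numeric vector of
#'   estimates (with `ses`), or a study table as returned by [read_studies()].
#' @param ses standard errors when `studies` is numeric.
#' @param level confidence level for the reported pooled interval.
#' @return Object of class `"fe_meta"`: list with the pooled
#'   [effect_estimate()], the `posterior` [normal_belief()], and the per-study
#'   inputs.
#' @examples
#' rec <- logodds_from_counts(95, 229, 283, 400, label = "RECOVERY")
#' rem <- logodds_from_counts(26, 79, 29, 63, label = "REMAP-CAP")
#' fixed_effect_meta(list(rec, rem))
#' @export
fixed_effect_meta <- function(studies, ses = NULL, level = 0.95) {
  studies <- as_estimate_list(studies, ses)
  if (length(studies) == 0L) stop("at least one study is required", call. = FALSE)
  post <- Reduce(forward_update, studies, init = normal_belief(0, 0))
  pooled <- effect_estimate(post$mean, 1 / sqrt(post$precision),
                            label = "pooled")
  structure(list(pooled = pooled, posterior = post, studies = studies,
                 level = level),
            class = "fe_meta")
}

#' @export
print.fe_meta <- function(x, digits = 3, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d studies\n", length(x$studies)))
  ci <- ci_from_estimate(x$pooled, level = x$level)
  cat(sprintf("  pooled estimate %s [%g%% CI %s to %s], precision %s\n",
              signif(x$pooled$estimate, digits), 100 * x$level,
              signif(ci$lower, digits), signif(ci$upper, digits),
              signif(x$posterior$precision, digits)))
  invisible(x)
}

#' Prior-predictive (Box) conflict check
#'
#' Measures conflict between a proper normal prior and an observed estimate by
#' locating the estimate in its prior-predictive distribution
#' `N(mu, sigma^2 + 1/delta)`.  The tail probability is
#' `p_box = Pr(chi^2_1 >= t_box^2)`, equivalently `2 * (1 - pnorm(|t_box|))`;
#' small values flag prior-data conflict.
#'
#' @param prior a [normal_belief()] with strictly positive precision.
#' @param data an [effect_estimate()].
#' @return Object of class `"box_check"`: list with `t_box` and `p_box`.
#' @examples
#' box_check(normal_belief(-0.26, 36.1), effect_estimate(-0.53, 0.145))
#' @export
box_check <- function(prior, data) {
  stopifnot(inherits(prior, "normal_belief"), inherits(data, "effect_estimate"))
  if (prior$precision <= 0)
    stop("the Box check needs a proper prior (precision > 0)", call. = FALSE)
  t_box <- (data$estimate - prior$mean) /
    sqrt(data$se^2 + 1 / prior$precision)
  structure(list(t_box = t_box,
                 p_box = pchisq(t_box^2, df = 1, lower.tail = FALSE)),
            class = "box_check")
}

#' @export
print.box_check <- function(x, digits = 3, ...) {
  cat(sprintf("Prior-predictive check: t_box = %s, p_box = %s\n",
              signif(x$t_box, digits), signif(x$p_box, digits)))
  invisible(x)
}

#' Leave-one-out prior-data conflict for a meta-analysis
#'
#' For each study, the meta-analytic estimate of the remaining studies serves
#' as the prior in a [box_check()].  Because fixed-effect pooling is conjugate
#' normal updating from a flat prior, the leave-one-out prior is obtained by
#' [reverse_update()] of the full pooled posterior rather than by re-fitting
#' n reduced meta-analyses.
#'
#' @param studies as in [fixed_effect_meta()] (at least two studies).
#' @param ses standard errors when `studies` is numeric.
#' @return A data frame with one row per study: label, estimate, se, two-sided
#'   p, leave-one-out prior mean and precision, `t_box` and `p_box`.
#' @export
leave_one_out_conflict <- function(studies, ses = NULL) {
  studies <- as_estimate_list(studies, ses)
  if (length(studies) < 2L)
    stop("leave-one-out conflict needs at least two studies", call. = FALSE)
  meta <- fixed_effect_meta(studies)
  rows <- lapply(seq_along(studies), function(i) {
    st <- studies[[i]]
    prior <- reverse_update(meta$posterior, st)
    bc <- box_check(prior, st)
    data.frame(study = if (is.null(st$label)) paste0("study", i) else st$label,
               estimate = st$estimate, se = st$se,
               p = test_statistics(st)$p,
               prior_mean = prior$mean, prior_precision = prior$precision,
               t_box = bc$t_box, p_box = bc$p_box,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
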