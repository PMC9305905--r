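#' Full Reverse-Bayes credibility report for a study table
#'
#' Orchestrates the package over a meta-analysis: pools the studies, runs the
#' leave-one-out prior-predictive conflict checks, performs the Analysis of
#' Credibility (interval and Bayes-factor flavours) per study with
#' prior-to-data conversion where counts are available, computes intrinsic
#' credibility, the fail-safe N of the pooled result, and false-positive-risk
#' bounds at the pooled p-value.
#'
#' Per-study Reverse-Bayes results that are undefined for a given finding (for
#' instance a sceptical prior for a non-significant study) are reported as
#' `NA` fields, not errors.
#'
#' @param table a `"study_table"` (see [read_studies()]) or compatible data
#'   frame.
#' @param alpha credibility level for interval-based AnCred.
#' @param gamma Bayes-factor cut-off for BF-based AnCred.
#' @param fpr target false positive risk for the prior-probability bounds.
#' @param calibrations calibrations reported in the FPR section.
#' @return Object of class `"ancred_report"`: a nested list with elements
#'   `pooled`, `conflict`, `studies`, `failsafe`, `fpr` and `config`.
#' @examples
#' rep <- run_report(corticosteroids_covid())
#' rep$studies$RECOVERY$sceptical$g  # 0.39
#' @export
run_report <- function(table, alpha = 0.05, gamma = 1 / 10, fpr = 0.05,
                       calibrations = c("local_z", "simple_z", "eplogp",
                                        "eqlogq")) {
  if (!inherits(table, "study_table"))
    table <- validate_study_table(as.data.frame(table))
  ests <- table_to_estimates(table)
  meta <- fixed_effect_meta(ests, level = 1 - alpha)
  pooled_ts <- test_statistics(meta$pooled)

  conflict <- if (length(ests) >= 2L) {
    leave_one_out_conflict(ests)
  } else {
    warning("single study: leave-one-out conflict section left empty")
    NULL
  }

  studies <- lapply(seq_along(ests), function(i) {
    est <- ests[[i]]
    ts <- test_statistics(est)
    rate <- if (table$.mode[i] == "counts") {
      # overall event rate for sceptical, control-arm rate for advocacy
      c(overall = (table$events_t[i] + table$events_c[i]) /
          (table$total_t[i] + table$total_c[i]),
        control = table$events_c[i] / table$total_c[i])
    }
    za <- qnorm(1 - alpha / 2)
    significant <- ts$z^2 > za^2
    side <- if (significant) {
      fit <- ancred(est, alpha = alpha,
                    rate = if (!is.null(rate)) rate[["overall"]])
      list(sceptical = c(list(g = fit$prior$g, tau2 = fit$prior$tau2,
                              SL = fit$prior$SL),
                         equivalent_fields(fit$equivalent)),
           advocacy = NULL)
    } else if (ts$z^2 < za^2) {
      fit <- ancred(est, alpha = alpha,
                    rate = if (!is.null(rate)) rate[["control"]])
      list(sceptical = NULL,
           advocacy = c(list(f = fit$prior$f, mu = fit$prior$mu,
                             tau = fit$prior$tau, AL = fit$prior$AL),
                        equivalent_fields(fit$equivalent)))
    } else list(sceptical = NULL, advocacy = NULL)
    ic <- intrinsic_credibility(est, alpha = alpha)
    chal <- sufficiently_sceptical_g(ts$z, gamma)
    c(list(estimate = est$estimate, se = est$se, z = ts$z, p = ts$p),
      side,
      list(intrinsic = list(p_ic = ic$p_ic, p_rep = ic$p_rep,
                            credibility_ratio = ic$credibility_ratio),
           bf = list(min_bf01_local = min_bf01_local(ts$z),
                     min_bf01_simple = min_bf01_simple(ts$z),
                     g_sceptical = chal$g,
                     bf12 = if (chal$exists) bf12_optimistic(ts$z, chal$g)
                            else NA_real_,
                     bf_ic = bf_ic(ts$z))))
  })
  names(studies) <- table$study_id

  fs <- if (abs(pooled_ts$z) > qnorm(1 - alpha / 2)) {
    f <- failsafe_n(meta$pooled, n_studies = length(ests),
                    total_precision = meta$posterior$precision, alpha = alpha)
    list(n_failsafe = f$n_failsafe, n_failsafe_int = f$n_failsafe_int,
         g = f$g)
  }

  fpr_bounds <- setNames(
    lapply(calibrations, function(cal)
      list(prior_bound = prior_for_fpr(fpr, pooled_ts$p, cal),
           prior_bound_fpr_equals_p = prior_for_fpr_equals_p(pooled_ts$p,
                                                             cal))),
    calibrations)

  structure(list(
    pooled = list(estimate = meta$pooled$estimate, se = meta$pooled$se,
                  precision = meta$posterior$precision,
                  or = exp(meta$pooled$estimate),
                  z = pooled_ts$z, p = pooled_ts$p,
                  ci = unclass(ci_from_estimate(meta$pooled,
                                                level = 1 - alpha))),
    conflict = conflict,
    studies = studies,
    failsafe = fs,
    fpr = fpr_bounds,
    config = list(alpha = alpha, gamma = gamma, fpr = fpr)),
    class = "ancred_report")
}

equivalent_fields <- function(eq) {
  if (is.null(eq)) return(NULL)
  list(equivalent = list(m = eq$m_int, n = eq$n_int, K = eq$K, R = eq$R,
                         m_exact = eq$m, n_exact = eq$n))
}

#' @export
print.ancred_report <- function(x, digits = 4, ...) {
  fmt <- function(v) formatC(signif(v, digits), format = "g", width = 9)
  cat("Reverse-Bayes credibility report\n")
  cat(sprintf("Pooled: %s [%s, %s], OR %s, p = %s (alpha = %g, gamma = %s)\n\n",
              fmt(x$pooled$estimate), fmt(x$pooled$ci$lower),
              fmt(x$pooled$ci$upper), fmt(x$pooled$or), fmt(x$pooled$p),
              x$config$alpha, signif(x$config$gamma, 3)))
  cat(sprintf("%-16s %9s %9s %9s %9s %9s\n",
              "study", "logOR", "se", "p", "t_box", "p_box"))
  for (id in names(x$studies)) {
    s <- x$studies[[id]]
    cf <- if (!is.null(x$conflict)) x$conflict[x$conflict$study == id, ]
    cat(sprintf("%-16s %9s %9s %9s %9s %9s\n", substr(id, 1, 16),
                fmt(s$estimate), fmt(s$se), fmt(s$p),
                if (!is.null(cf) && nrow(cf)) fmt(cf$t_box) else "",
                if (!is.null(cf) && nrow(cf)) fmt(cf$p_box) else ""))
  }
  if (!is.null(x$failsafe))
    cat(sprintf("\nFail-safe N: %s (ceiling %d)\n",
                fmt(x$failsafe$n_failsafe), x$failsafe$n_failsafe_int))
  invisible(x)
}

#' Serialise a credibility report to JSON
#'
#' Numbers are written at full double precision; the text rendering of the
#' report (see `print`) is the lossy view.
#'
#' @param report an `"ancred_report"`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ancred_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
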