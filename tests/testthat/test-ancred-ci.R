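test_that("sufficiently sceptical prior reproduces the corticosteroid numbers", {
  sp <- sceptical_prior(recovery())
  expect_near(sp$g, 0.39, 0.005)
  expect_near(sp$SL, 0.178, 0.001)

  pooled <- sceptical_prior(effect_estimate(-0.42, 0.11))
  expect_near(pooled$SL, 0.13, 0.005)

  expect_error(sceptical_prior(remap_cap()), "not significant")
})

test_that("both scepticism-limit routes give one value and the posterior sits at zero", {
  set.seed(21)
  for (i in 1:40) {
    alpha <- runif(1, 0.01, 0.2)
    est <- random_estimate(significant = TRUE, alpha = alpha)
    sp <- sceptical_prior(est, alpha = alpha)
    ci <- ci_from_estimate(est, level = 1 - alpha)
    sl_interval <- (ci$upper - ci$lower)^2 /
      (4 * sqrt(abs(ci$upper * ci$lower)))
    expect_near(sp$SL, sl_interval, tolerance = 1e-10)

    # conjugate update of N(0, g sigma^2): null-side posterior limit is 0
    post <- forward_update(normal_belief(0, 1 / sp$tau2), est)
    za <- qnorm(1 - alpha / 2)
    null_side <- post$mean + sign(est$estimate) * (-za) / sqrt(post$precision)
    expect_near(null_side, 0, 1e-8)
  }
})

test_that("advocacy prior reproduces REMAP-CAP and fixes its null quantile at zero", {
  ap <- advocacy_prior(remap_cap())
  expect_near(ap$AL, -1.89, 0.005)
  expect_equal(ap$cv, 1 / qnorm(0.975), tolerance = 1e-12)

  # zero estimate: f = 2 but the prior collapses onto zero
  ap0 <- advocacy_prior(effect_estimate(0, 0.3))
  expect_equal(ap0$f, 2)
  expect_equal(ap0$mu, 0)
  expect_equal(ap0$AL, 0)

  expect_error(advocacy_prior(recovery()), "significant")

  set.seed(22)
  for (i in 1:40) {
    alpha <- runif(1, 0.01, 0.2)
    est <- random_estimate(significant = FALSE, alpha = alpha)
    if (abs(est$estimate) < 1e-8) next
    ap <- advocacy_prior(est, alpha = alpha)
    za <- qnorm(1 - alpha / 2)
    # prior quantile toward the null is exactly 0
    prior_null_q <- ap$mu - sign(est$estimate) * za * ap$tau
    expect_equal(prior_null_q, 0, tolerance = 1e-10)
    # and the posterior touches 0 from the credible side
    post <- forward_update(normal_belief(ap$mu, 1 / ap$tau^2), est)
    null_side <- post$mean - sign(ap$mu) * za / sqrt(post$precision)
    expect_near(null_side, 0, 1e-8)
  }
})

test_that("intrinsic credibility: pIC, prep and their exact coupling", {
  rec <- intrinsic_credibility(recovery())
  expect_near(rec$p_ic, 0.01, 0.002)
  expect_near(rec$p_rep, 0.995, 0.001)
  expect_true(rec$intrinsically_credible)

  rem <- intrinsic_credibility(remap_cap())
  expect_near(rem$p_ic, 0.46, 0.005)
  expect_near(rem$p_rep, 0.77, 0.005)
  expect_false(rem$intrinsically_credible)

  null <- intrinsic_credibility(effect_estimate(0, 1))
  expect_near(null$p_ic, 1)
  expect_equal(null$p_rep, 0.5)

  set.seed(23)
  for (i in 1:30) {
    ic <- intrinsic_credibility(random_estimate())
    expect_lt(abs(ic$p_rep + ic$p_ic / 2 - 1), 1e-15)
    expect_gte(ic$p_rep, 0.5)
  }
})

test_that("credibility ratio: printed example, strict boundary, pBox equivalence", {
  cr <- credibility_ratio(-0.82, -0.25)
  expect_near(cr$ratio, 3.27, 0.01)
  expect_true(cr$intrinsically_credible)

  expect_false(credibility_ratio(-5.8, -1)$intrinsically_credible)
  expect_error(credibility_ratio(-0.2, 0.4), "undefined")

  # the ratio rule is the pBox self-challenge in disguise: the exact boundary
  # is z = sqrt(2) z_{a/2}, i.e. ratio (sqrt(2)+1)/(sqrt(2)-1) = 5.83; spot
  # check agreement on a z grid clear of the narrow 5.80-5.83 rounding band
  za <- qnorm(0.975)
  for (z in c(2.1, 2.3, 2.5, 2.7, 2.76, 2.78, 3, 3.5, 4.5)) {
    if (abs(z - sqrt(2) * za) < 0.005) next
    est <- effect_estimate(z * 0.3, 0.3)
    ci <- ci_from_estimate(est, 0.95)
    ratio_rule <- credibility_ratio(ci)$ratio < 5.83
    g <- sceptical_prior(est)$g
    pbox_rule <- pchisq(z^2 / (1 + g), 1, lower.tail = FALSE) < 0.05
    expect_identical(ratio_rule, pbox_rule)
  }
})

test_that("analytic p-value thresholds for intrinsic credibility", {
  th <- intrinsic_p_thresholds(0.05)
  expect_near(th$p_matthews, 0.013, 5e-4)
  expect_near(th$p_box, 0.0056, 1e-4)

  # the Box threshold equals the p whose z is sqrt(2) z_{a/2} (self-challenge
  # boundary), checked against a numeric root
  za <- qnorm(0.975)
  z_star <- uniroot(function(z) z^2 / (1 + sceptical_prior(
    effect_estimate(z, 1))$g) - qchisq(0.95, 1), c(za * 1.01, 6))$root
  expect_near(th$p_box, 2 * pnorm(z_star, lower.tail = FALSE),
               tolerance = 1e-6)

  alphas <- c(0.005, 0.01, 0.05, 0.1, 0.2)
  ms <- vapply(alphas, function(a) intrinsic_p_thresholds(a)$p_matthews, 0.0)
  bs <- vapply(alphas, function(a) intrinsic_p_thresholds(a)$p_box, 0.0)
  expect_true(all(diff(ms) > 0) && all(diff(bs) > 0))
})

test_that("fail-safe N: closed form, iterative oracle and metafor agree", {
  fs <- failsafe_n(effect_estimate(-0.42, 0.11), n_studies = 7,
                   total_precision = 83.8)
  expect_near(fs$g, 0.36, 0.005)
  expect_near(fs$n_failsafe, 19.5, 0.5)
  expect_equal(fs$n_failsafe_int, fs$n_iterative)

  # independent implementation: Rosenberg's fail-safe N in metafor
  tab <- corticosteroids_covid()
  meta <- fixed_effect_meta(tab)
  ests <- vapply(table_to_estimates_for_test(tab), function(e) e$estimate, 0.0)
  ses <- vapply(table_to_estimates_for_test(tab), function(e) e$se, 0.0)
  fs2 <- failsafe_n(meta$pooled, n_studies = 7,
                    total_precision = meta$posterior$precision)
  rosenberg <- metafor::fsn(ests, vi = ses^2, type = "Rosenberg")$fsnum
  expect_equal(fs2$n_failsafe_int, as.numeric(rosenberg))
  expect_equal(fs2$n_failsafe_int, fs2$n_iterative)

  # barely significant pooled estimate needs almost no null studies
  za <- qnorm(0.975)
  tiny <- failsafe_n(effect_estimate(za * 0.1 * (1 + 1e-6), 0.1),
                     n_studies = 5, total_precision = 100)
  expect_lt(tiny$n_failsafe, 1e-4)

  expect_error(failsafe_n(remap_cap(), 7, 83.8), "not significant")
})
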