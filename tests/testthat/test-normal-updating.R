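test_that("forward updating is precision-weighted averaging", {
  # flat prior: posterior equals the likelihood
  post <- forward_update(normal_belief(0, 0), effect_estimate(0.7, 0.2))
  expect_near(post$mean, 0.7)
  expect_equal(post$precision, 1 / 0.04)

  # leave-one-out prior plus RECOVERY recovers the pooled result
  post <- forward_update(normal_belief(-0.26, 36.1), recovery())
  expect_near(post$mean, -0.42, 0.005)
  expect_near(post$precision, 83.8, 0.1)

  set.seed(7)
  for (i in 1:50) {
    prior <- random_belief()
    data <- random_estimate()
    post <- forward_update(prior, data)
    # independent oracle: weighted mean with precision weights
    w <- c(prior$precision, 1 / data$se^2)
    expect_near(post$mean,
                 weighted.mean(c(prior$mean, data$estimate), w),
                 tolerance = 1e-12)
    expect_equal(post$precision, sum(w), tolerance = 1e-12)
  }
})

test_that("reverse updating inverts the forward step", {
  prior <- reverse_update(normal_belief(-0.42, 83.8), recovery())
  expect_near(prior$precision, 36.1, 0.1)
  expect_near(prior$mean, -0.26, 0.01)

  set.seed(8)
  for (i in 1:100) {
    p0 <- random_belief()
    d <- random_estimate()
    p1 <- reverse_update(forward_update(p0, d), d)
    expect_equal(p1$mean, p0$mean, tolerance = 1e-10)
    expect_equal(p1$precision, p0$precision, tolerance = 1e-10)
  }

  # posterior barely above the observational precision: prior is the residual
  d <- effect_estimate(0.3, 0.5)
  kappa <- 1 / 0.25
  pr <- reverse_update(normal_belief(0.3, kappa + 1e-6), d)
  expect_equal(pr$precision, 1e-6, tolerance = 1e-9)
  expect_near(pr$mean, 0.3, 1e-6)

  expect_error(reverse_update(normal_belief(0, 2), effect_estimate(0, 0.5)),
               "not invertible")
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  studies <- list(recovery(), remap_cap())
  meta <- fixed_effect_meta(studies)
  expect_near(meta$pooled$estimate, -0.50, 0.005)
  expect_near(meta$posterior$precision, 57.6, 0.1)

  # oracle + exact precision additivity
  ks <- vapply(studies, function(s) 1 / s$se^2, 0.0)
  xs <- vapply(studies, function(s) s$estimate, 0.0)
  expect_near(meta$pooled$estimate, sum(xs * ks) / sum(ks),
               tolerance = 1e-14)
  expect_identical(meta$posterior$precision, sum(ks))

  single <- fixed_effect_meta(list(recovery()))
  expect_equal(single$pooled$estimate, recovery()$estimate)
  expect_equal(single$pooled$se, recovery()$se, tolerance = 1e-12)

  set.seed(9)
  many <- replicate(6, random_estimate(), simplify = FALSE)
  ref <- fixed_effect_meta(many)
  for (i in 1:5) {
    perm <- fixed_effect_meta(sample(many))
    expect_equal(perm$pooled$estimate, ref$pooled$estimate,
                 tolerance = 1e-12)
    expect_equal(perm$posterior$precision, ref$posterior$precision,
                 tolerance = 1e-12)
  }

  expect_error(fixed_effect_meta(list()), "at least one")
})

test_that("Box prior-predictive check flags conflict as printed", {
  bc <- box_check(normal_belief(-0.26, 36.1), recovery())
  expect_near(bc$t_box, -1.24, 0.01)
  expect_near(bc$p_box, 0.22, 0.01)

  # no conflict at all when the estimate sits on the prior mean
  none <- box_check(normal_belief(0.4, 10), effect_estimate(0.4, 0.3))
  expect_near(none$t_box, 0)
  expect_equal(none$p_box, 1)

  expect_error(box_check(normal_belief(0, 0), recovery()), "proper prior")

  # chi-square-1 tail and two-sided normal tail are the same number
  bc2 <- box_check(normal_belief(0.1, 4), effect_estimate(-0.6, 0.25))
  expect_equal(bc2$p_box, 2 * pnorm(abs(bc2$t_box), lower.tail = FALSE),
               tolerance = 1e-14)
})

test_that("box_check tail probability is calibrated (Monte Carlo)", {
  set.seed(11)
  prior <- normal_belief(-0.26, 36.1)
  data <- recovery()
  bc <- box_check(prior, data)
  n <- 1e6
  theta <- rnorm(n, prior$mean, 1 / sqrt(prior$precision))
  x <- rnorm(n, theta, data$se)
  t_sim <- (x - prior$mean) / sqrt(data$se^2 + 1 / prior$precision)
  emp <- mean(abs(t_sim) >= abs(bc$t_box))
  se_bin <- sqrt(bc$p_box * (1 - bc$p_box) / n)
  expect_lt(abs(emp - bc$p_box), 3 * se_bin)
})

test_that("leave-one-out conflict equals explicit re-pooling", {
  tab <- corticosteroids_covid()
  conf <- leave_one_out_conflict(tab)
  expect_near(conf$p_box[conf$study == "RECOVERY"], 0.22, 0.01)

  # oracle: re-fit the reduced meta-analysis for every study
  ests <- lapply(seq_len(nrow(tab)), function(i) {
    logodds_from_counts(tab$events_t[i], tab$total_t[i] - tab$events_t[i],
                        tab$events_c[i], tab$total_c[i] - tab$events_c[i])
  })
  for (i in seq_along(ests)) {
    reduced <- fixed_effect_meta(ests[-i])
    oracle <- box_check(reduced$posterior, ests[[i]])
    expect_equal(conf$t_box[i], oracle$t_box, tolerance = 1e-10)
    expect_equal(conf$p_box[i], oracle$p_box, tolerance = 1e-10)
  }

  twin <- list(effect_estimate(0.3, 0.2), effect_estimate(0.3, 0.2))
  expect_equal(leave_one_out_conflict(twin)$t_box, c(0, 0))

  expect_error(leave_one_out_conflict(list(recovery())), "at least two")
})
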