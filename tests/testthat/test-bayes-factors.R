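rec_z <- function() abs(test_statistics(recovery())$z)

test_that("BF01 under the sceptical prior: limits, printed value, grid minimum", {
  expect_equal(bf01_sceptical(c(0, 1.5, 4), 0), c(1, 1, 1))
  z <- rec_z()
  expect_near(bf01_sceptical(z, 0.59), 1 / 10, 0.005)

  # dense-grid oracle for the minimiser g* = max(z^2 - 1, 0)
  gs <- seq(0, 40, length.out = 1e4)
  for (zi in c(0.5, 1, 2, 3, 4)) {
    vals <- bf01_sceptical(zi, gs)
    g_star <- max(zi^2 - 1, 0)
    expect_near(min(vals), bf01_sceptical(zi, g_star), 1e-5)
    expect_near(min(vals), min_bf01_local(zi), 1e-5)
    # unimodal: decreasing then increasing around the minimiser
    expect_true(all(diff(vals[gs < g_star]) < 0))
    expect_true(all(diff(vals[gs > g_star + 1e-3]) > 0))
  }
})

test_that("minimum Bayes factors: printed values, continuity, ordering", {
  expect_near(1 / min_bf01_local(rec_z()), 148.9, 0.1)
  expect_equal(min_bf01_local(1), 1)
  expect_near(min_bf01_local(1 + 1e-9), 1, 1e-6)  # continuous at |z| = 1

  z_rem <- abs(test_statistics(remap_cap())$z)
  expect_near(1 / min_bf01_simple(z_rem), 1.7, 0.05)
  expect_equal(min_bf01_simple(0), 1)

  zs <- seq(0, 6, by = 0.01)
  expect_true(all(min_bf01_simple(zs) <= min_bf01_local(zs) + 1e-15))
  for (g in c(0.1, 1, 5)) {
    expect_true(all(min_bf01_local(zs) <= bf01_sceptical(zs, g) + 1e-12))
  }
})

test_that("Lambert-W sufficiently sceptical g: roots, plug-back, existence", {
  # the internal branch solver satisfies the defining identity, including
  # close to the branch point -1/e, and agrees with pracma's W_{-1}
  for (y in -c(1e-4, 0.01, 0.1, 0.25, 1 / exp(1) - 1e-6, 1 / exp(1) - 1e-13)) {
    pair <- ancred:::lambert_w_pair(y)
    expect_lte(pair[1], -1)
    expect_gte(pair[2], -1)
    for (w in pair) expect_near(w * exp(w), y, 1e-12)
  }
  for (y in -c(0.01, 0.1, 0.3)) {
    expect_near(ancred:::lambert_w_pair(y)[1], pracma::lambertWn(y), 1e-9)
  }

  ch <- sufficiently_sceptical_g(rec_z(), 1 / 10)
  expect_true(ch$exists)
  expect_near(ch$g, 0.59, 0.005)
  expect_near(ch$z_gamma, sqrt(-2 * log(1 / 10)), 1e-12)

  set.seed(61)
  for (i in 1:25) {
    z <- runif(1, 0.2, 5)
    gamma <- runif(1, 0.02, 0.9)
    ch <- sufficiently_sceptical_g(z, gamma)
    expect_identical(ch$exists, min_bf01_local(z) <= gamma)
    if (ch$exists) {
      for (root in ch$g_roots) {
        expect_near(bf01_sceptical(z, root), gamma, 1e-8)
      }
      # roots bracket the minimiser whenever distinct and z^2 > 1
      if (z^2 > 1 && diff(ch$g_roots) > 1e-8) {
        expect_lt(ch$g_roots[1], z^2 - 1)
        expect_gt(ch$g_roots[2], z^2 - 1)
      }
    }
  }

  # cut-off below the attainable minimum: no sceptical prior exists
  expect_false(sufficiently_sceptical_g(2, 1 / 100)$exists)
})

test_that("BF12 against the optimistic prior matches its density-ratio form", {
  z <- rec_z()
  g <- sufficiently_sceptical_g(z, 1 / 10)$g
  expect_near(1 / bf12_optimistic(z, g), 64, 0.5)
  expect_equal(bf12_optimistic(0, 1), 1)

  set.seed(62)
  for (i in 1:20) {
    est <- random_estimate()
    gi <- runif(1, 0.05, 5)
    # prior-predictive densities at the estimate under the two priors
    d_sceptical <- dnorm(est$estimate, 0, est$se * sqrt(1 + gi))
    d_optimistic <- dnorm(est$estimate, est$estimate, est$se * sqrt(2))
    expect_equal(bf12_optimistic(est$estimate / est$se, gi),
                 d_sceptical / d_optimistic, tolerance = 1e-12)
  }
})

test_that("Bayes factor for intrinsic credibility across its three regimes", {
  expect_near(1 / bf_ic(rec_z()), 25, 0.5)
  expect_near(1 / bf_ic(1.96), 2.1, 0.05)
  expect_near(1 / bf_ic(2.77), 5.7, 0.1)

  # undefined below sqrt(log 2)
  expect_true(is.na(bf_ic(0.5)))
  expect_true(is.na(bf_ic(sqrt(log(2)) - 1e-6)))

  # equals the minimum Bayes factor up to the breakpoint (about 2.04), and is
  # strictly more conservative beyond it
  zs_low <- seq(sqrt(log(2)) + 1e-3, 2.03, length.out = 15)
  expect_equal(bf_ic(zs_low), min_bf01_local(zs_low), tolerance = 1e-12)
  zs_high <- seq(2.05, 5, length.out = 15)
  expect_true(all(bf_ic(zs_high) > min_bf01_local(zs_high)))

  # at the crossing, BF01 and BF12 coincide at the reported value
  z <- rec_z()
  crossing <- function(g) log((1 + g) / sqrt(2)) - z^2 * (g - 1) / (2 * (1 + g))
  g <- uniroot(crossing, c(1 + 1e-9, z^2 - 1), tol = 1e-12)$root
  expect_near(bf01_sceptical(z, g), bf12_optimistic(z, g), 1e-9)
  expect_near(bf_ic(z), bf01_sceptical(z, g), 1e-9)
})

test_that("Bayes-factor advocacy prior reproduces the CAPE COVID rescue", {
  fit <- advocacy_bf_prior(cape_covid(), gamma = 1 / 3)
  expect_true(fit$exists)
  expect_near(fit$cv, 1 / 1.5, 0.01)
  f <- fit$roots$f[fit$chosen]
  expect_near(f, 0.37, 0.01)
  expect_near(fit$roots$mu[fit$chosen], -0.29, 0.01)
  expect_near(fit$roots$tau[fit$chosen], 0.2, 0.01)
  other <- fit$roots[-fit$chosen, ]
  expect_near(other$f, 1.26, 0.02)
  expect_near(other$tau, 0.67, 0.02)

  # plug-back: both priors leave the Bayes factor exactly at the cut-off
  est <- cape_covid()
  for (i in seq_len(nrow(fit$roots))) {
    mu <- fit$roots$mu[i]
    tau2 <- fit$roots$tau[i]^2
    bf <- sqrt(1 + tau2 / est$se^2) *
      exp(-0.5 * (est$estimate^2 / est$se^2 -
                    (est$estimate - mu)^2 / (est$se^2 + tau2)))
    expect_near(bf, 1 / 3, 1e-8)
  }

  # below the simple-alternative bound nothing can rescue the finding
  z <- test_statistics(cape_covid())$z
  expect_false(advocacy_bf_prior(cape_covid(),
                                 gamma = min_bf01_simple(z) * 0.9)$exists)
})
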