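#' Bayes factor under a mean-zero normal sceptical prior
#'
#' For a normal likelihood with test statistic `z` and a sceptical prior
#' `N(0, g * sigma^2)` under the alternative, the Bayes factor comparing the
#' point null to the alternative is
#' \deqn{BF_{01} = \sqrt{1+g}\,\exp\!\left(-\frac{g}{1+g}\frac{z^2}{2}\right).}
#' It tends to 1 as `g -> 0` (null and alternative indistinguishable) and to
#' infinity as `g -> Inf` (Jeffreys-Lindley), with a minimum at
#' `g = max(z^2 - 1, 0)`.  All Bayes-factor functions are symmetric in the
#' sign of `z`.
#'
#' @param z test statistic (vectorised).
#' @param g non-negative relative prior variance (vectorised).
#' @return the Bayes factor(s) `BF01`.
#' @examples
#' bf01_sceptical(3.69, 0.59)  # ~ 1/10
#' @export
bf01_sceptical <- function(z, g) {
  stopifnot(all(g >= 0))
  sqrt(1 + g) * exp(-(g / (1 + g)) * z^2 / 2)
}

#' Minimum Bayes factor over mean-zero normal (local) alternatives
#'
#' The smallest value of [bf01_sceptical()] over all `g >= 0`:
#' `|z| exp(-z^2/2) sqrt(e)` for `|z| > 1`, and 1 otherwise (the minimiser
#' `g = z^2 - 1` hits the boundary at `|z| = 1`; both branches agree there).
#'
#' @param z test statistic (vectorised).
#' @return the minimum Bayes factor(s), in (0, 1].
#' @examples
#' min_bf01_local(3.69)  # ~ 1/149
#' @export
min_bf01_local <- function(z) {
  az <- abs(z)
  ifelse(az > 1, az * exp(-az^2 / 2) * sqrt(exp(1)), 1)
}

#' Minimum Bayes factor over all simple alternatives
#'
#' The classical bound `exp(-z^2/2)`, attained by the alternative that puts
#' all mass on the observed estimate.  No prior can rescue a finding beyond
#' this bound.
#'
#' @param z test statistic (vectorised).
#' @return `exp(-z^2/2)`.
#' @examples
#' min_bf01_simple(1.05)  # ~ 1/1.7
#' @export
min_bf01_simple <- function(z) exp(-z^2 / 2)

#' Sufficiently sceptical relative prior variance at a Bayes-factor cut-off
#'
#' Solves `BF01(z, g) = gamma` for the relative prior variance by the
#' Lambert-W representation
#' \deqn{g = -z^2/q - 1, \quad q = W\!\left(-\frac{z^2}{\gamma^2} e^{-z^2}\right),}
#' where the branch with `W(y) <= -1` gives the sceptic's (smaller) root and
#' the principal branch the second, diffuse root — two solutions always exist
#' when any does, a footprint of the Jeffreys-Lindley paradox.  Solutions
#' exist iff `min_bf01_local(z) <= gamma`.
#'
#' @param z test statistic.
#' @param gamma Bayes-factor cut-off in (0, 1), e.g. 1/10 for strong evidence.
#' @return Object of class `"bf_challenge"`: list with `exists`, `g` (the
#'   smaller root, NA if none), `g_roots` (both roots), `gamma`, `z`, and
#'   `z_gamma = sqrt(-2 log gamma)`.
#' @examples
#' sufficiently_sceptical_g(3.69, gamma = 1/10)  # g = 0.59
#' @export
sufficiently_sceptical_g <- function(z, gamma) {
  stopifnot(length(z) == 1L, is.finite(z),
            length(gamma) == 1L, gamma > 0, gamma < 1)
  az <- abs(z)
  out <- structure(list(gamma = gamma, z = az,
                        z_gamma = sqrt(-2 * log(gamma)),
                        exists = FALSE, g = NA_real_,
                        g_roots = c(NA_real_, NA_real_)),
                   class = "bf_challenge")
  if (min_bf01_local(az) > gamma) return(out)
  y <- -az^2 * exp(-az^2) / gamma^2   # in [-1/e, 0) exactly when roots exist
  q <- lambert_w_pair(y)              # (W_{-1}, W_0): sceptic's and diffuse root
  roots <- sort(pmax(-az^2 / q - 1, 0))
  out$exists <- TRUE
  out$g <- roots[1L]
  out$g_roots <- roots
  out
}

#' @export
print.bf_challenge <- function(x, digits = 3, ...) {
  cat(sprintf("Sceptical-prior challenge at gamma = %s\n", signif(x$gamma, digits)))
  if (!x$exists) {
    cat(sprintf("  no sufficiently sceptical prior exists (minBF01 = %s > gamma)\n",
                signif(min_bf01_local(x$z), digits)))
  } else {
    cat(sprintf("  g roots: %s (sceptic's bound) and %s\n",
                signif(x$g_roots[1], digits), signif(x$g_roots[2], digits)))
  }
  invisible(x)
}

#' Bayes factor contrasting the sceptical with the optimistic prior
#'
#' The optimistic prior `N(theta_hat, sigma^2)` is the flat-prior posterior —
#' the position of a proponent taking the original claim at face value.
#' Contrasting the sceptical prior (hypothesis 1) with it (hypothesis 2)
#' yields
#' \deqn{BF_{12} = \sqrt{\frac{2}{1+g}}\exp\!\left(-\frac{z^2}{2(1+g)}\right),}
#' the ratio of the two prior-predictive densities at the observed estimate.
#'
#' @param z test statistic (vectorised).
#' @param g positive relative variance of the sceptical prior (vectorised).
#' @return the Bayes factor(s) `BF12`.
#' @examples
#' bf12_optimistic(3.69, 0.59)  # ~ 1/64
#' @export
bf12_optimistic <- function(z, g) {
  stopifnot(all(g > 0))
  sqrt(2 / (1 + g)) * exp(-z^2 / (2 * (1 + g)))
}

# Both real branches of the Lambert W function on [-1/e, 0): returns
# c(W_{-1}(y), W_0(y)).  Solved by bracketed root finding on w e^w = y with a
# Newton polish; the quadratic branch-point series takes over where Newton's
# derivative (1 + w) e^w degenerates.  (General-purpose W implementations can
# fail to converge this close to the branch point, and the sufficiently
# sceptical variance needs exactly this neighbourhood when gamma approaches
# the minimum Bayes factor.)
lambert_w_pair <- function(y) {
  stopifnot(y < 0, y >= -exp(-1) * (1 + 1e-12))
  y <- max(y, -exp(-1))  # clamp floating-point undershoot of the branch point
  disc <- 2 * (exp(1) * y + 1)
  if (disc < 1e-12) {    # branch point: both branches meet at -1
    p <- sqrt(max(disc, 0))
    return(c(-1 - p, -1 + p))
  }
  f <- function(w) w * exp(w) - y
  w0 <- uniroot(f, c(-1, 0), tol = 1e-14)$root
  lo <- -2
  while (f(lo) < 0) lo <- lo * 2   # w e^w -> 0- as w -> -Inf, so f -> -y > 0
  wm <- uniroot(f, c(lo, -1), tol = 1e-14)$root
  polish <- function(w) {
    for (i in 1:3) w <- w - (w * exp(w) - y) / ((1 + w) * exp(w))
    w
  }
  if (abs(1 + w0) > 1e-6) w0 <- polish(w0)
  if (abs(1 + wm) > 1e-6) wm <- polish(wm)
  c(wm, w0)
}

# z value where the BF01 = BF12 crossing first appears; the crossing equation
# log((1+g)/sqrt(2)) = z^2 (g-1) / (2 (1+g)) has its extremum in g at
# g = z^2 - 1, so tangency occurs where log(z^2) - z^2/2 + 1 - log(sqrt(2)) = 0
bf_ic_breakpoint <- function() {
  if (is.null(.ancred_cache$z_break)) {
    .ancred_cache$z_break <- uniroot(
      function(z) log(z^2) - z^2 / 2 + 1 - log(sqrt(2)),
      c(1.5, 3), tol = 1e-12)$root
  }
  .ancred_cache$z_break
}

#' Bayes factor for intrinsic credibility
#'
#' The smallest cut-off `gamma` at which intrinsic credibility can be
#' established: the data must support the optimistic prior over the
#' sufficiently sceptical prior at least as strongly as they support the
#' sceptical prior over the null (`BF12 <= BF01`).  Undefined for
#' `|z| < sqrt(log 2)` (any sceptical prior then beats the optimistic one).
#' For `sqrt(log 2) <= |z| <` the breakpoint (about 2.04) it equals
#' [min_bf01_local()]; beyond the breakpoint it is the common value of
#' `BF01` and `BF12` at the crossing `BF01(g) = BF12(g)`, located by bracketed
#' root finding in `g` on `(1, z^2 - 1]`.
#'
#' @param z test statistic (vectorised).
#' @return the Bayes factor(s); `NA` where undefined.
#' @examples
#' bf_ic(3.69)  # ~ 1/25
#' bf_ic(1.96)  # ~ 1/2.1
#' @export
bf_ic <- function(z) {
  vapply(z, function(zi) {
    az <- abs(zi)
    if (!is.finite(az) || az < sqrt(log(2))) return(NA_real_)
    zb <- bf_ic_breakpoint()
    if (az < zb) return(min_bf01_local(az))
    crossing <- function(g) log((1 + g) / sqrt(2)) - az^2 * (g - 1) / (2 * (1 + g))
    # crossing() is positive at g -> 1+ and negative at the extremum g = z^2-1
    # once az > breakpoint; take the smaller root
    g <- uniroot(crossing, c(1 + 1e-12, az^2 - 1), tol = 1e-10)$root
    bf01_sceptical(az, g)
  }, 0.0)
}

#' Advocacy prior in the Bayes-factor framework
#'
#' Finds the normal prior `N(mu, tau^2)` under the alternative that renders a
#' non-compelling finding just compelling at Bayes-factor cut-off `gamma`.
#' With both parameters free the problem is underdetermined, so the prior's
#' coefficient of variation is fixed at `CV = tau/|mu| = 1/z_gamma` with
#' `z_gamma = sqrt(-2 log gamma)` — the prior then carries the evidential
#' weight of data whose simple-alternative minimum Bayes factor equals
#' `gamma`.  The remaining free parameter is the relative mean
#' `f = mu / theta_hat`; `BF01(f) = gamma` typically has two roots, and the
#' root with `f` closest to zero is designated as the more conservative
#' choice.  No prior can push the Bayes factor below [min_bf01_simple()], so
#' `gamma` must exceed that bound.
#'
#' @param est an [effect_estimate()] (or numeric estimate with `se`).
#' @param gamma Bayes-factor cut-off in (0, 1).
#' @param se standard error when `est` is numeric.
#' @param f_max upper end of the search range for the relative mean.
#' @return Object of class `"advocacy_bf_prior"`: list with `exists`, `roots`
#'   (data frame of `f`, `mu`, `tau`), index `chosen`, `cv`, `z_gamma`,
#'   `gamma`.
#' @examples
#' cape <- logodds_from_counts(11, 64, 20, 53)  # CAPE COVID, reconstructed
#' advocacy_bf_prior(cape, gamma = 1/3)          # f = 0.37 and f' = 1.26
#' @export
advocacy_bf_prior <- function(est, gamma, se = NULL, f_max = 50) {
  est <- as_effect_estimate(est, se)
  stopifnot(length(gamma) == 1L, gamma > 0, gamma < 1)
  z <- est$estimate / est$se
  z_gamma <- sqrt(-2 * log(gamma))
  cv <- 1 / z_gamma
  out <- structure(list(gamma = gamma, z_gamma = z_gamma, cv = cv,
                        exists = FALSE,
                        roots = data.frame(f = numeric(), mu = numeric(),
                                           tau = numeric()),
                        chosen = NA_integer_, estimate = est),
                   class = "advocacy_bf_prior")
  if (gamma <= min_bf01_simple(z)) return(out)  # cannot be rescued that far

  sigma2 <- est$se^2
  bf01_f <- function(f) {
    mu <- f * est$estimate
    tau2 <- (cv * mu)^2
    sqrt(1 + tau2 / sigma2) *
      exp(-0.5 * (est$estimate^2 / sigma2 -
                    (est$estimate - mu)^2 / (sigma2 + tau2)))
  }
  # BF01(0) = 1 > gamma; a dip below gamma between 0 and the diffuse regime
  # produces two roots bracketing the minimiser
  opt <- optimize(bf01_f, c(0, f_max))
  if (opt$objective > gamma) return(out)
  hi <- opt$minimum
  while (bf01_f(hi) < gamma && hi < 1e6) hi <- hi * 2
  if (bf01_f(hi) < gamma)
    stop("failed to bracket the second advocacy root", call. = FALSE)
  f1 <- uniroot(function(f) bf01_f(f) - gamma, c(1e-12, opt$minimum),
                tol = 1e-12)$root
  f2 <- uniroot(function(f) bf01_f(f) - gamma, c(opt$minimum, hi),
                tol = 1e-12)$root
  roots <- data.frame(f = c(f1, f2), mu = c(f1, f2) * est$estimate,
                      tau = abs(c(f1, f2) * est$estimate) * cv)
  out$exists <- TRUE
  out$roots <- roots
  out$chosen <- which.min(abs(roots$f))
  out
}

#' @export
print.advocacy_bf_prior <- function(x, digits = 3, ...) {
  cat(sprintf("Bayes-factor advocacy prior at gamma = %s (CV = %s)\n",
              signif(x$gamma, digits), signif(x$cv, digits)))
  if (!x$exists) {
    cat("  no normal prior can render the finding compelling at this cut-off\n")
  } else {
    for (i in seq_len(nrow(x$roots)))
      cat(sprintf("  %sf = %s: mu = %s, tau = %s\n",
                  if (i == x$chosen) "* " else "  ",
                  signif(x$roots$f[i], digits), signif(x$roots$mu[i], digits),
                  signif(x$roots$tau[i], digits)))
    cat("  (* conservative choice: relative mean closest to zero)\n")
  }
  invisible(x)
}
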