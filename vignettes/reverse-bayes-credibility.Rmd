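---
title: "Reverse-Bayes credibility analysis with ancred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-Bayes credibility analysis with ancred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancred)
```

## The idea

Bayes' theorem is usually run forward: choose a prior, observe data, read off
the posterior.  Run backward, it answers a different and often more useful
question: *which prior would an observer have to hold for this finding to
lose (or gain) credibility?*  If that prior is absurd in the light of external
knowledge, the finding stands; if it is plausible, the finding is fragile.
The package implements this Reverse-Bayes programme for effect estimates that
are approximately normal on some analysis scale — for two-arm binary-outcome
trials, the log odds ratio $\hat\theta$ with standard error $\sigma$ and test
statistic $z = \hat\theta/\sigma$.

Everything in the package conditions on the normal likelihood
$\hat\theta \sim N(\theta, \sigma^2)$.  That is the standard meta-analysis
approximation; it is accurate for moderately large trials and degrades for
very small cell counts (no continuity correction is applied — a zero cell is
an error, not a patched number).

## Conjugate updating, meta-analysis and conflict diagnostics

Beliefs are stored as mean and *precision* $(\mu, \delta)$, so the flat prior
of fixed-effect pooling is exactly representable as $\delta = 0$.  Forward
updating with an observation of precision $\kappa = 1/\sigma^2$ is

$$\delta' = \delta + \kappa, \qquad
  \mu' = \frac{\mu\delta + \hat\theta\kappa}{\delta'},$$

and `reverse_update()` inverts it, defined while $\delta' > \kappa$.
Fixed-effect meta-analysis is a fold of `forward_update()` over the studies;
`leave_one_out_conflict()` exploits the inversion to obtain each study's
leave-one-out prior *without* refitting, and scores prior–data conflict with
the prior-predictive (Box) tail probability

$$t_{Box} = \frac{\hat\theta_i - \mu_{-i}}
  {\sqrt{\sigma_i^2 + 1/\delta_{-i}}}, \qquad
  p_{Box} = \Pr(\chi^2_1 \ge t_{Box}^2).$$

The equality of the shortcut and the explicit re-fit is pinned by a test; the
$\chi^2_1$ tail is computed directly, which coincides with the two-sided
normal tail of $|t_{Box}|$.

```{r}
meta <- fixed_effect_meta(corticosteroids_covid())
meta
leave_one_out_conflict(corticosteroids_covid())[, c(1, 2, 4, 7, 8)]
```

## Analysis of Credibility

`ancred()` is the central fit.  For a finding significant at level $\alpha$
it derives the *sufficiently sceptical prior*: mean-zero, with relative
variance

$$g = \frac{\tau^2}{\sigma^2} = \frac{1}{z^2/z^2_{\alpha/2} - 1},$$

tuned so the posterior equal-tailed interval just touches no effect.  Its
$1-\alpha/2$ quantile magnitude is the scepticism limit, computable two ways
(both exposed, their equality tested):

$$SL = \frac{(U-L)^2}{4\sqrt{|UL|}} = z_{\alpha/2}\,\sqrt{g}\,\sigma.$$

For a non-significant finding the *advocacy prior* plays the mirror role: its
quantile toward the null is pinned at zero, its coefficient of variation is
fixed at $1/z_{\alpha/2}$, and its far quantile — the advocacy limit
$AL = 2\mu = 4\hat\theta/(1 - z^2/z^2_{\alpha/2})\cdot\tfrac12$ — bounds the
family of priors able to rescue the finding.  Negative estimates are handled
by mirroring: $SL$ is reported as a positive magnitude, $AL$ carries the sign
of the estimate.  Exactly at the significance boundary both constructions are
undefined and the package says so rather than returning a limit value.

```{r}
rec <- logodds_from_counts(95, 229, 283, 400, label = "RECOVERY")
fit <- ancred(rec, rate = 378 / 1007)
summary(fit)
```

## Prior weight as a hypothetical trial

A prior variance is abstract; the same evidence expressed as a trial is not.
Matching the sceptical prior variance $\tau^2$ to the log-OR variance
$2/m + 2/n$ of a balanced trial with event rate $R$ matched to the study
gives $m = 2/(\tau^2(1-R))$, $n = m(1-R)/R$.  Advocacy priors have non-zero
mean, encoded as an unequal allocation $1{:}K$ with $K = e^{AL/2}$ and
variance $2/m + (K+1)/n$.  Reported counts are nearest-integer roundings of
the exact reals (both kept; nearest-integer is what reproduces the published
389/648 and 11/25 tables), and `equivalent_study_variance()` closes the loop.
The fail-safe $N$ of a pooled estimate is the same idea pointed at
publication bias: $N = n/(\delta'\tau^2)$, with a brute-force augmentation
count kept alongside as a cross-check (they agree after ceiling, and with the
Rosenberg fail-safe number).

## Borrowing with mixture priors

`reverse_bayes_weight()` asks how much prior weight an informative component
(say, a larger trial's posterior) must get — against a weak unit-information
component, variance 4 on the log-OR scale — before a non-significant finding
becomes credible.  The exposed parameter is the weight on the *informative*
component, the quantity advocates must justify; intervals are equal-tailed
(not HPD), and the mixture quantile is found by bracketed root finding on the
mixture CDF to $10^{-10}$, with the bracket grown geometrically from the
component-quantile envelope if needed.  Monotonicity of the null-side limit
in the weight is verified on a grid before the root search; if it ever
failed, all crossings would be located and the smallest returned with a
warning.

## Bayes-factor flavour

With evidence measured by Bayes factors instead of posterior intervals, the
sceptical prior gives

$$\mathrm{BF}_{01} = \sqrt{1+g}\;
  \exp\!\Big(-\frac{g}{1+g}\frac{z^2}{2}\Big),$$

minimised at $g = \max(z^2-1, 0)$ (the local minimum Bayes factor
$|z|e^{-z^2/2}\sqrt{e}$).  Fixing $\mathrm{BF}_{01} = \gamma$ and solving for
$g$ needs both real branches of the Lambert $W$ function; the two roots are a
footprint of the Jeffreys–Lindley paradox.  The branches are solved
internally by bracketed root finding on $we^w = y$ with a Newton polish and a
series expansion at the branch point $-1/e$ — the neighbourhood that matters
precisely when $\gamma$ approaches the minimum Bayes factor, and where
general-purpose $W$ routines can fail to converge.  The solver is validated
in the tests against the defining identity and against an independent
$W_{-1}$ implementation.

The second Bayes factor $\mathrm{BF}_{12}$ contrasts the sceptical prior with
the *optimistic* prior $N(\hat\theta, \sigma^2)$; intrinsic credibility at
cut-off $\gamma$ requires $\mathrm{BF}_{12} \le \mathrm{BF}_{01}$.  The
level-free summary $\mathrm{BF}_{IC}$ is the smallest such $\gamma$: it is
undefined for $|z| < \sqrt{\log 2}$, equals the minimum Bayes factor up to a
breakpoint, and beyond it is the common value at the crossing
$\mathrm{BF}_{01}(g) = \mathrm{BF}_{12}(g)$, i.e. the root of
$\log\{(1+g)/\sqrt2\} = z^2(g-1)/\{2(1+g)\}$ on $(1, z^2-1]$.  The crossing
equation's stationary point in $g$ sits at $g = z^2 - 1$, which pins the
breakpoint as the root of $\log z^2 - z^2/2 + 1 - \log\sqrt2 = 0$, located
once by bisection ($z \approx 2.039$) and cached.  This reconstruction
reproduces all published values ($1/25$ at the RECOVERY $z$, $1/2.1$ at
$z=1.96$, $1/5.7$ at $z=2.77$); a closed form may exist but is not needed.

```{r}
z <- abs(test_statistics(rec)$z)
c(one_over_minBF = 1 / min_bf01_local(z),
  g = sufficiently_sceptical_g(z, 1 / 10)$g,
  one_over_BFIC = 1 / bf_ic(z))
```

## False positive risk

The false positive risk is the posterior probability of the point null given
the observed two-sided $p$ (the "p-equals" reading).  Reverse-Bayes turns the
usual computation around: given $p$ and a target FPR, `prior_for_fpr()`
bounds the prior null probability by
$[1 + \{(1-\mathrm{FPR})/\mathrm{FPR}\}\,\mathrm{minBF}(p)]^{-1}$.  Four
calibrations supply the minimum Bayes factor: the local $z$-based bound; the
simple-alternatives $z$-based bound for the two-sided test with direction
taken into account, $\min(1,\,2e^{-z^2/2})$ — this, not the one-sided
$e^{-z^2/2}$ kept as `min_bf01_simple()` in the Bayes-factor module, is what
reproduces the published two-sided bounds (57% at $p=0.005$, and 15.2%/11.4%
under FPR $=p$); and the $p$-based $-ep\log p$ and $-eq\log q$ calibrations.
Each saturates at 1 beyond its cut-off; the calibration set is an enum so the
$t$-based variant could be added.

## The synthetic generator and what it does (not) show

`generate_fixture()` emulates the study conditions of the worked example: by
default 7 two-arm binomial trials, true log odds ratio $-0.42$, control-arm
event rate 0.38 (the corticosteroids trials' overall mortality), arm sizes
drawn uniformly between 20 and 700 patients — spanning the size imbalance of
that meta-analysis.  Degenerate draws are redrawn a bounded number of times;
determinism is guaranteed by a single seed.  The generator draws from the
exact model the methods assume (common fixed effect, independent binomials),
so the coverage and calibration tests it feeds validate internal consistency
— they cannot detect failures of the normal approximation in tiny trials,
between-study heterogeneity, or publication bias, none of which the
fixed-effect machinery models.  The packaged seven-trial table is a
reconstruction from the published forest plot: three rows are confirmed
against independently reported counts, the other four are approximate (they
reproduce the published pooled precision 83.8, log-OR $-0.42$ and all
conflict diagnostics, which is what the examples need).

## Numerical and design choices

* Tie-breaks at boundaries are strict: $z^2 = z^2_{\alpha/2}$ leaves both
  AnCred priors undefined; a credibility ratio of exactly 5.8 is not
  credible.  (The exact ratio boundary is $(\sqrt2+1)/(\sqrt2-1) \approx
  5.83$; 5.8 is the conventional rounded rule and the package follows it.)
* Root finding uses plain bracketed `uniroot` at tolerances $10^{-9}$ to
  $10^{-14}$; every solved quantity has a plug-back test.
* Effects are kept on the log-OR scale internally; odds ratios appear only in
  printed output via `exp()`.
* Test problem sizes: the Monte-Carlo calibration of $p_{Box}$ uses $10^6$
  draws (three binomial standard errors of slack); parameter-recovery uses
  1000 seeded replicates of the default 7-trial generator, requiring the
  nominal-95% two-standard-error coverage to stay above 93%.

## Limitations

Only normal likelihoods and normal (or two-component normal mixture) priors
are supported; heavier-tailed robust priors, exact binomial or $t$
likelihoods, random-effects pooling and replication-study assessments are out
of scope.  The fail-safe N quantifies robustness to unseen null studies but
neither detects nor corrects publication bias.
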