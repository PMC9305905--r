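# ancred — Reverse-Bayes Analysis of Credibility

Statistical findings are usually summarised by whether they cleared a
significance threshold.  `ancred` turns Bayes' theorem around to ask the more
informative question: **which prior would a sceptic — or an advocate — have to
hold for this finding to change status?**  If making a significant result
non-credible requires a prior nobody could defend, the result is robust; if a
modest prior rescues a non-significant one, dismissing it as "no effect" is
premature.  The package is aimed at meta-analysts, trialists and
methodologists working with effect estimates that are approximately normal on
some scale (log odds ratios for two-arm binary outcomes).

## What it computes

For an estimate $\hat\theta$ with standard error $\sigma$ and
$z=\hat\theta/\sigma$:

* **Sceptical prior / scepticism limit** for significant findings: the
  mean-zero normal prior with relative variance
  $g = 1/(z^2/z_{\alpha/2}^2-1)$ whose posterior just touches no effect, and
  its prior quantile $SL = (U-L)^2/(4\sqrt{|UL|})$.
* **Advocacy prior / advocacy limit** for non-significant findings: the
  null-anchored prior with relative mean $f = 2/(1-z^2/z_{\alpha/2}^2)$ and
  fixed coefficient of variation $1/z_{\alpha/2}$ that just makes the finding
  credible; $AL = 2f\hat\theta$.
* **Intrinsic credibility**: $p_{IC} = 2\{1-\Phi(|z|/\sqrt2)\}$, the
  replication-direction probability $p_{rep} = 1-p_{IC}/2$, the 5.8
  credibility-ratio rule and the analytic thresholds (0.013 and 0.0056 at
  $\alpha=0.05$).
* **Prior-to-data conversion**: the hypothetical two-arm trial (events $m$,
  non-events $n$, allocation $K$) carrying the same evidential weight as a
  Reverse-Bayes prior, plus the fail-safe-N equivalence
  $N = n_{\text{studies}}/(\delta'\tau^2)$.
* **Fixed-effect meta-analysis** by conjugate normal updating, with
  leave-one-out prior-predictive (Box) conflict checks via exact reverse
  updating.
* **Bayes-factor AnCred**: $BF_{01}$ under sceptical priors, minimum Bayes
  factors, the Lambert-W solution for the sufficiently sceptical variance,
  the sceptical-vs-optimistic $BF_{12}$, the Bayes factor for intrinsic
  credibility $BF_{IC}$, and Bayes-factor advocacy priors.
* **Mixture borrowing**: the smallest weight on an informative prior
  component that renders a non-significant finding credible.
* **False positive risk**: Reverse-Bayes bounds on the prior null probability
  from four p-value calibrations, including the FPR = p fallacy conditions.

## Worked example

The running example is the seven-trial meta-analysis of corticosteroids and
COVID-19 mortality (packaged as `corticosteroids_covid()`).  The RECOVERY
trial reported 95/324 deaths under dexamethasone versus 283/683 under usual
care:

```r
library(ancred)
rec <- logodds_from_counts(95, 229, 283, 400, label = "RECOVERY")
fit <- ancred(rec, rate = 378 / 1007)
summary(fit)
#> Analysis of Credibility: RECOVERY
#>   estimate -0.534 (se 0.145), z = -3.69, p = 0.000224 -> significant at alpha = 0.05
#> Sufficiently sceptical prior (mean 0)
#>   relative variance g = 0.393, tau^2 = 0.00822
#>   scepticism limit SL = 0.178 (prior 95% interval +-SL)
#> Intrinsic credibility: p_IC = 0.00907, p_rep = 0.995
#>   credibility ratio = 3.27 (< 5.8)
#>   intrinsically credible at alpha = 0.05: TRUE
#> Equivalent prior study (sceptical)
#>   m = 389 events and n = 648 non-events in both arms (1037 patients each)
#>   matched event rate R = 0.375, prior variance tau^2 = 0.00822
```

Reading: to dismiss RECOVERY a sceptic must rule out mortality-odds
reductions beyond $e^{-0.178} \approx 16\%$ a priori — prior evidence worth a
trial of 2074 patients with 389 deaths per arm, twice the size of RECOVERY
itself.  A replication would go in the same direction with probability 0.995.
The Bayes-factor flavour agrees:

```r
z <- abs(test_statistics(rec)$z)
c(one_over_minBF = 1 / min_bf01_local(z),
  g = sufficiently_sceptical_g(z, 1 / 10)$g,
  one_over_BFIC = 1 / bf_ic(z))
#> one_over_minBF              g  one_over_BFIC
#>    148.8779276      0.5933339     25.3079265

fixed_effect_meta(corticosteroids_covid())
#> Fixed-effect meta-analysis of 7 studies
#>   pooled estimate -0.417 [95% CI -0.631 to -0.203], precision 83.8
```

A thin command-line front end is installed with the package
(`system.file("cli", "ancred.R", package = "ancred")`), e.g.

```sh
Rscript inst/cli/ancred.R challenge --counts 95,324,283,683 --rate 0.3754
Rscript inst/cli/ancred.R fpr --p 0.005 --fpr 0.05 --calibration local_z
```

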