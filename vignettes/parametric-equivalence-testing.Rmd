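---
title: "Parametric equivalence and non-inferiority testing of survival curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric equivalence and non-inferiority testing of survival curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nphequiv)
```

## The problem

Showing that a test treatment is *not worse* (non-inferiority) or *neither
worse nor better by a relevant amount* (equivalence) than a reference is a
different task from detecting a difference. For time-to-event endpoints the
standard machinery — log-rank tests and Cox models — summarizes the contrast
in a single hazard ratio and presumes that ratio constant over time. When
survival curves cross, that assumption fails visibly and the single-number
summary becomes meaningless.

`nphequiv` takes a parametric route that needs no proportional-hazards
assumption. Each arm's event-time distribution is modelled by a parametric
family (Weibull, exponential, log-logistic, log-normal, Gaussian or
logistic), fitted by censored-data maximum likelihood. The treatment
contrast is then a *function of time*, either

* the survival difference \(\Delta(t) = S_1(t,\theta_1) - S_2(t,\theta_2)\), or
* the log hazard ratio \(r(t) = \log\{h_1(t,\theta_1)/h_2(t,\theta_2)\}\),

and hypotheses are formulated against a clinically chosen margin
(\(\delta\) for the survival difference, typically 0.1–0.2;
\(\varepsilon\) for the log hazard ratio), pointwise at a time \(t_0\) or
uniformly over an interval \([t_1, t_2]\).

## Model, bands, tests

**Likelihood.** For arm \(\ell\) with observations \((t_{\ell j},
\delta_{\ell j})\), events contribute \(\log f_\ell(t_{\ell j})\) and
censored observations \(\log S_\ell(t_{\ell j})\). The censoring
distribution factorizes out; its own likelihood is the same expression with
the indicators flipped, which is how `fit_censoring_model()` is implemented.
The observed information (numerically differentiated negative Hessian at the
MLE, in the family's natural parameterization) is kept with each fit; its
inverse is the full-sample covariance, already carrying the \(1/n_\ell\)
scaling.

**Delta-method bands.** The asymptotic variance of the estimated contrast is
\[
\hat\sigma^2(t) \;=\; g_1(t)^\top I_{\hat\theta_1}^{-1} g_1(t)
              \;+\; g_2(t)^\top I_{\hat\theta_2}^{-1} g_2(t),
\]
with \(g_\ell\) the gradient of \(S_\ell(t,\cdot)\) (or \(\log
h_\ell(t,\cdot)\)) at \(\hat\theta_\ell\). Gradients are analytic for the
Weibull and exponential families and central finite differences (relative
step \(10^{-6}\)) otherwise; the two paths are unit-tested against each
other on the Weibull. One-sided \((1-\alpha)\) pointwise bands are
\(\hat\Delta(t) \mp z_{1-\alpha}\,\hat\sigma(t)\).

**Parametric bootstrap.** Alternatively \(\hat\sigma^2(t)\) is the empirical
variance of the contrast across replicates generated from the *fitted* event
and censoring models (censoring times drawn from the fitted censoring
distribution, administrative cap applied when the design had one), with the
event models refitted per replicate. This requires censoring models but no
variance formula, and is the practical choice for very small samples.

**Intersection–union tests.** Non-inferiority
(\(H_0\colon \Delta(t_0) \ge \delta\)) is rejected iff the upper band
satisfies \(U(t_0) \le \delta\); equivalence
(\(H_0\colon |\Delta(t_0)| \ge \delta\)) iff additionally
\(L(t_0) \ge -\delta\). Both use the *same* \((1-\alpha)\) one-sided bands —
the intersection–union principle makes this an asymptotic \(\alpha\)-level
test without any multiplicity adjustment, a property the test suite checks
empirically on the null boundary. Interval-wise hypotheses over
\([t_1,t_2]\) reject iff every pointwise test on the evaluation grid
rejects, i.e. \(\max_t U(t) \le \delta\) and \(\min_t L(t) \ge -\delta\);
the continuum is approximated by the band's grid, whose density is the
caller's responsibility. Comparisons are boundary-inclusive. A consequence
of the construction is that simultaneous (wider) confidence bands are not
needed for a valid interval-wise test.

**Conventions worth knowing.** At \(\alpha = 0.05\) the two one-sided 95%
bands displayed together form a two-sided 90% interval; that is the interval
the worked examples print. Coverage studies, by contrast, evaluate the
two-sided \((1-\alpha)\) interval (z at \(1-\alpha/2\)), so their nominal
target is 0.95. The non-parametric comparator builds the same object from
Kaplan–Meier curves with Greenwood variances (events precede censorings at
ties) and feeds the identical decision code, so method comparisons share
every line of the test logic.

## The simulation harness and its presets

`scenario_config()` bundles the data-generating designs used by the
operating-characteristic studies; `generate_trial()` draws a two-arm trial
(per subject: event time \(Y\), censoring time \(C\), observation
\(\min(Y, C, t_{max})\), event indicator \(Y \le \min(C, t_{max})\)) and
`estimate_operating_characteristics()` Monte-Carlo-estimates rejection
rates or band coverage. Trials are seeded individually from the master
seed, so results are independent of execution order.

* **PH** (proportional hazards): reference arm Weibull(shape 1.5, scale
  3.4) with Exp(0.1) censoring; test arm Weibull(1.5, 4.9) with Exp(0.09)
  for type-I-error/coverage studies, Weibull(1.5, 3.7) with Exp(0.05) for
  power; administrative cutoff 9 months; default grid 23 points on
  [1.5, 6]. The reference-arm censoring is ≈25%. The printed test-arm
  rates are kept as stated even though they work out to ≈34% and ≈16%
  censoring rather than the nominal ≈25% (the rates, not the nominal
  percentage, define the preset; swapping them would give ≈24%/25%, and
  the harness accepts custom rates for anyone wanting that variant).
* **NPH** (crossing curves): test arm Weibull(2, 2.5) with Exp(0.14)
  (type I) or Weibull(2, 3.4) with Exp(0.1) (power); grid 14 points on
  [1.5, 4]. Here the rate-to-configuration assignment was chosen so that
  both arms censor ≈25%, which we verified by integration.
* **LL-misspec**: both arms log-logistic — scale 2.6/shape 1.5 vs scale
  3.9/shape 2.1, the reading under which the hazard ratio spans ≈2.5→0.8
  over [1, 5] months — with uniform censoring on \([0, c_\ell]\), where
  \(c_\ell\) is calibrated numerically at configuration time to a ≈20%
  censoring fraction; the analysis family stays Weibull by design, making
  this the event-model-misspecification stress test.

What the generator emulates: random right censoring plus an administrative
cutoff, independent arms, smooth parametric event times. What it does not:
covariates, dependent censoring, interval censoring, delayed entry, or the
heterogeneity of real trial populations — so passing operating
characteristics here demonstrate correctness of the machinery under the
stated models, not robustness to everything a real trial can do.

## Numerical choices

* Positive parameters are optimized on the log scale (unconstrained
  problem); the Weibull profile-likelihood in the shape reduces the fit to
  a one-dimensional search with a closed-form scale, and the exponential
  MLE is closed-form. Remaining families use BFGS with moment-based
  starting values and up to five jittered restarts.
* The observed information is computed in the natural parameterization by
  central differences; a fit whose information is numerically singular
  (reciprocal condition number below \(10^{-12}\)) raises an error rather
  than returning a garbage variance.
* All survival/density evaluations run on the log scale to avoid underflow
  in the tails; \(\hat\sigma^2\) is clamped at 0 to absorb roundoff.
* Bootstrap replicates without a single event (possible at tiny \(n\)) are
  redrawn; more than 10% such failures abort the run. Simulated trials that
  fail to fit are counted and reported; more than 5% abort.
* Test times must lie on the band's grid — the package never interpolates
  silently.
* The uniform censoring bound for the LL-misspec preset solves
  \(\int_0^c S(u)\,du / c = 0.2\) by `uniroot` on an integral evaluated
  with `integrate`.

## Design decisions that were genuinely open

* **Log-logistic parameterization.** The family is parameterized as
  (scale, shape) with \(S(t) = 1/(1 + (t/\text{scale})^{\text{shape}})\),
  the standard form in which the scale equals the median; a printed
  negative exponent in one source formula is treated as a typo.
* **Tie convention.** If an event time equals a censoring time the subject
  counts as an event (censored only when the censoring time is strictly
  smaller); at tied observed times in the KM estimate, events precede
  censorings.
* **Observed vs expected information.** The full-sample observed
  information is used everywhere; no expected-information integrals are
  computed. This is both cheaper and closer to the data.
* **Earliest-rejection reporting.** For interval non-inferiority the
  package reports the earliest grid time from which the pointwise
  condition holds through the end of the interval — the quantity a trial
  report would quote ("non-inferior from day 96 onward").

## Problem sizes used by the checks

The packaged checks use the study's own simulation sizes where the
quantities are study-level (1000 trials for power and level cells, 500
replicates for asymptotic coverage, 200 replicates × 200 bootstrap draws
for bootstrap coverage, \(10^5\) subjects for the censoring-calibration
check), and smaller sizes (tens to hundreds of replicates) for purely
mechanical properties where the assertion does not depend on fourth-digit
precision.

## Known limitations

* Correct specification of the event-time family matters: under the
  LL-misspec preset the Weibull-based bands undercover at small samples
  and the tests can inflate the type-I error for generous margins. Model
  selection via `model_selection_aic()` is the built-in mitigation; a
  prespecified-model setting cannot use it.
* The interval-wise test is a finite-grid approximation of a continuum
  statement; a very coarse grid can only make it anti-conservative in the
  gaps between grid points.
* No covariate adjustment, no simultaneous bands, no restricted-mean or
  Mann–Whitney effect measures — the contrast menu is exactly
  \(\Delta(t)\) and \(r(t)\).

## A worked example

```{r, eval = FALSE}
set.seed(1)
cfg <- scenario_config("ph-power", n1 = 200, n2 = 200)
d <- generate_trial(cfg)
d1 <- d[d$group == 1, ]; d2 <- d[d$group == 2, ]

f1 <- fit_event_model(d1$time, d1$event, "weibull")
f2 <- fit_event_model(d2$time, d2$event, "weibull")
band <- pointwise_bands(f1, f2, grid = seq(0.5, 6, by = 0.25), alpha = 0.05)

pointwise_test(band, t0 = 2, margin = 0.15, type = "equivalence")
interval_test(band, margin = 0.2, type = "noninferiority")
```
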