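---
title: "Healthy longevity distributions: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Healthy longevity distributions: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hldist)
```

## The model

`hldist` treats healthy longevity after age 60 as the accumulated reward
of an absorbing Markov chain over single ages 60–89. Two independent
stochastic processes drive it: mortality, through the annual death
probability $q_x$, and health, through the probability $h_x$ of being
healthy at age $x$ estimated from cross-sectional prevalence. Each year
contributes a Bernoulli($h_x$) healthy-year reward; total healthy years
$HY$ therefore lie in $[0, 30]$, the cap reflecting an age-90 limit:
anyone still healthy at exact age 90 is treated as exiting there. The
exit age (age at health loss) is $60 + HY$, so its distribution lives on
the 31 integer ages 60–90.

Because the model is prevalence-based it is intrinsically
cross-sectional: it does not model transitions back to health (an
individual contributes healthy years according to the age-specific
*probability* of being healthy, not an incidence process), and the same
$q_x$ applies to healthy and unhealthy individuals. Both are known
limitations of this model class; in reality unhealthy people die at
higher rates, which biases the late-age composition.

### Reward timing and conditioning

The literature on Markov chains with rewards leaves two conventions
open, and the package implements both:

* **occupancy** (default): anyone alive at exact age $x$ earns the year's
  reward, independent of surviving the year;
* **survived-year**: the reward is earned only if the year $x \to x+1$ is
  survived, giving first moments never above the occupancy ones.

Backward recursions for the first three raw moments follow from
$E[(B + S\,R')^k]$ (occupancy) and $E[S^k (B + R')^k]$ (survived-year)
with $B \sim \mathrm{Bern}(h_x)$, $S \sim \mathrm{Bern}(1 - q_x)$ and
$R'$ the reward from age $x+1$ on, all independent. We deliberately use
the scalar backward recursion rather than the equivalent
$(I - U^\top)^{-1}$ matrix formulation: for a pure age chain they are
identical, and the scalar form is easier to verify line by line. Under
occupancy timing the first moment collapses algebraically to the
classical Sullivan sum $\sum_x \ell_x h_x$, which `sullivan_hle()`
computes independently and the tests compare to $10^{-12}$.

By default results are conditioned on being healthy at 60
(`condition_on_healthy_at_60 = TRUE`, replacing $h_{60}$ by 1), because
the distributions are meant to describe people who reach age 60 in good
health. Neither convention choice is guaranteed to reproduce any
particular published set of estimates whose exact convention is
unstated; the Monte-Carlo simulator `simulate_healthy_years()`, which
implements the stochastic model path by path, is the arbiter of internal
consistency for both.

## Maximum entropy on a discrete support

Among all distributions on ages 60–90 with the given first three
moments, the entropy maximizer is the exponential family
$p_x \propto \exp(\lambda_1 z_x + \lambda_2 z_x^2 + \lambda_3 z_x^3)$.
Numerical choices:

* **Discrete support.** The 31 integer atoms match the integer reward
  totals exactly ($\text{exit age} = 60 + HY$); no continuity
  correction is applied. Continuous densities are a presentation device
  only and are out of scope.
* **Standardized basis.** $z_x = (x - \mu)/\sigma$ with $\mu, \sigma$
  from the target moments. A raw-age cubic spans five orders of
  magnitude and makes the dual Hessian numerically singular; the
  standardized basis keeps it well conditioned and makes the targets
  simply $(0, 1, \text{skewness})$.
* **Solver.** Newton minimization of the convex dual
  $\log Z(\lambda) - \langle \lambda, t\rangle$ from $\lambda = 0$ (the
  uniform distribution), Hessian equal to the covariance of the basis
  under $p(\lambda)$, Armijo backtracking with an epsilon slack so the
  final steps do not stall when the dual decrease falls below machine
  precision. Tolerance $10^{-8}$ on the standardized moment residuals,
  at most 200 iterations; non-convergence is an error carrying
  diagnostics, never a silent fallback.
* **Feasibility.** Before solving, the mean exit age must lie in
  $[60, 90]$ and the variance below the exact two-point bound
  $(\mu - 60)(90 - \mu)$; violations raise a feasibility error naming
  the bound. A zero-variance moment set short-circuits to a point mass
  at the nearest support age, and its skewness is reported as undefined
  rather than $0/0$.
* **Mode.** Ties in $\arg\max_x p_x$ are broken to the smallest age (a
  documented, arbitrary rule; with 31 distinct atoms real ties are
  vanishingly rare).

Three-moment maximum entropy is an approximation: against the
Monte-Carlo exit-age distribution of the same schedules it thins the
old-age tail and fattens some younger ages. `tail_diagnostic()` reports
the per-age signed differences and total variation distance so this is
visible rather than hidden; a fourth moment would reduce the
discrepancy but is not implemented here.

## Comparison statistics

`phi_hl()` evaluates the outsurvival probability with the half-weighted
tie term; closing the sum with $lhealth_{91} = 0$ enforces the age-90
cap. It assumes independence of the two populations — spouses'
correlated health violates this in real applications. `hellinger()`
evaluates both textbook forms, the difference form
$\sqrt{2\sum(\sqrt{p}-\sqrt{q})^2}$ and the Bhattacharyya form
$2\sqrt{1 - \sum\sqrt{pq}}$, and raises an error if their squares
disagree beyond $10^{-12}$ (a genuine implementation bug would show up
as an $O(1)$ disagreement). The *returned* value is the difference
form: near identical distributions the Bhattacharyya route computes
$1 - BC$ by catastrophic cancellation and can report $\sim 10^{-8}$
where the true distance is $0$, while the difference form is exact
there. On distinct distributions the two agree to $10^{-12}$ and the
choice is immaterial. With the scaling used here the distance is
bounded by 2, attained exactly for disjoint supports.

## Survey preparation choices

Health measures follow three modes: free of every listed condition, at
most one condition, and a cognitive threshold (every test score above
the reference mean minus 1.5 reference SDs *and* no dementia/Alzheimer's
diagnosis). Points the source definitions leave open, and the choices
made:

* **Cognitive reference population.** Reference means and SDs are pooled
  over all person-wave observations and both sexes by default; a
  per-wave option exists (`cognition_reference = "by-wave"`). Pooling is
  the more literal reading of "all observations" and keeps thresholds
  comparable across waves.
* **Per-test rule.** Each of the three tests (time orientation, verbal
  fluency, memory) is compared with its own threshold; failing any one
  test marks the record unhealthy. No composite score is defined.
* **Missingness.** Records with all cognitive scores missing are dropped
  (with a logged count); a missing individual test is simply not
  evaluated. Missing condition indicators drop the record by default;
  `missing_conditions = "absent"` treats them as condition-free for
  sensitivity analyses.
* **Ages.** Analysis is restricted to ages 60+; ages 90+ form an
  open-ended group excluded from $h_x$ estimation because the model
  needs ages 60–89 only.

Prevalence is the calibrated-weight share of healthy respondents per
(wave, sex, age) stratum; it is invariant to rescaling all weights in a
stratum, and both unweighted and Kish effective stratum sizes are
reported. Mortality pooling across countries weights each country's
$q_x$ by its (weighted) respondent count for that stratum.

## Bootstrap

Sampling error is attached to the prevalence estimates only; mortality
schedules are held fixed. For each (group × age) stratum of size $n$,
each replicate redraws $n$ records with replacement; replicate $r$ uses
seed $\text{base} + r$, so single replicates are reproducible and
independent of the total count. "Weighted sampling with replacement"
admits two estimators, and both are shipped:

* `scheme = "selection"` (default, the literal reading): selection
  probability proportional to the calibrated weight, replicate
  prevalence = unweighted mean. This treats the weights as exact
  selection probabilities; when weights are heterogeneous *and*
  independent of health status it understates the sampling variance of
  the weighted point estimator by roughly the factor
  $n_{\text{eff}}/n$, so its intervals can slightly under-cover.
* `scheme = "reweight"`: uniform resampling with weighted recomputation —
  the classical bootstrap of the estimator actually reported. The
  nominal-coverage check in the acceptance suite runs under this scheme,
  because coverage is a property of bootstrapping the estimator itself.

Intervals are empirical percentiles (2.5th/97.5th at the default 95%)
with R's type-7 linear interpolation between order statistics; the mode
age, an integer, snaps each endpoint to the nearest attained replicate
value. The default replicate count is 5,000; tests and examples scale
down to 200, which is ample for the structural checks performed there.
Replicates whose maximum-entropy fit fails are dropped and counted, and
a run fails outright if more than 1% drop.

## The synthetic world

The generator produces the statistical *structure* the pipeline assumes,
with defaults fixed once:

* **Mortality:** Gompertz hazards mapped to annual probabilities via
  $q_x = 1 - \exp\{-a e^{b(x-60)}\}$ (always $< 1$). Defaults
  $a = 0.010, b = 0.095$ (male) and $a = 0.0055, b = 0.100$ (female) are
  loosely typical of recent European period mortality above 60.
* **Health prevalence:** declining logistic curves
  $h_x = \text{floor} + (1-\text{floor})/(1 + e^{k(x - x_0)})$;
  per-condition default midpoints and floors mimic broad European survey
  age patterns (hypertension early and common, stroke and Parkinson's
  rare, arthritis shifted earlier for women, lung disease and diabetes
  for men). These are plausibility values, not estimates.
* **Weights:** lognormal (meanlog 0, sdlog 0.5), strictly positive and
  deliberately *not* normalized within strata — calibrated weights need
  not sum to the sample size.
* **Conditions:** independent Bernoulli draws per condition. The joint
  distribution of conditions within a person is an assumption the
  sources do not constrain; independence is the default and the
  indicator-level measures (`all-free`, `at-most-one`) are exercised
  under it.
* **Cognition and dementia:** test scores decline linearly with age
  around education-specific means (SD 1); the diagnosis probability
  grows exponentially from 0.2% at 60. Defaults put roughly 5–15% of the
  oldest respondents below the −1.5 SD rule.

What the generator does **not** emulate: attrition and non-response,
country heterogeneity, correlated conditions (a frailty switch is a
possible extension), interviewer and panel-conditioning effects, and any
calibration to real survey margins. A green test therefore establishes
that the pipeline's algebra, numerics and error handling are correct
under the stated stochastic model — not that real-world estimates from
restricted data are reproduced.

`simulate_healthy_years()` is the package's independent oracle: it
simulates the exact chain forward, path by path, and the tests require
the analytic moments to sit within four Monte-Carlo standard errors at
$10^6$ paths for both timing conventions, alongside an exact
dynamic-programming cross-check in the test suite.

## Known limitations

* Average mortality shared by healthy and unhealthy individuals; no
  recovery to health — both inherent to prevalence-based models.
* Three-moment maximum entropy underestimates old-age health-loss
  probabilities (see `tail_diagnostic()`); four moments would help but
  are out of scope.
* The outsurvival statistic assumes independent populations.
* The `selection` bootstrap scheme can under-cover with strongly
  heterogeneous weights; use `reweight` when coverage matters.
* Unimodality is expected but not enforced; a heavily multimodal truth
  would need more than three moments to be captured.
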