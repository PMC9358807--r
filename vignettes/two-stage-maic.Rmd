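---
title: "Anchored population adjustment with one- and two-stage MAIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored population adjustment with one- and two-stage MAIC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maic2s)
```

## The problem

Health-technology assessment frequently has to compare two active
treatments, A and B, that were never evaluated head to head: A was compared
with a common comparator C in the *index* trial, for which the analyst
holds individual patient data (IPD), and B was compared with C in a
*competitor* trial, for which only published aggregate-level data (ALD) are
available — baseline covariate means, and an unadjusted B-vs-C effect
estimate with its standard error. The anchored indirect comparison
estimates the A-vs-B effect in the competitor-study population as

\[
\hat\Delta_{AB} = \hat\Delta_{AC} - \hat\Delta_{BC},
\qquad
\widehat{V}(\hat\Delta_{AB}) = \widehat{V}(\hat\Delta_{AC}) + \widehat{V}(\hat\Delta_{BC}),
\]

the variances being summed because the two within-trial estimates are
independent. The difficulty is $\hat\Delta_{AC}$: covariates that modify
the A-vs-C effect on the linear-predictor scale are generally distributed
differently in the two trials, so the index trial's own marginal estimate
does not transport to the competitor population.

## One-stage weighting (MAIC)

Matching-adjusted indirect comparison reweights the index-trial subjects so
that the weighted means of the selected effect modifiers equal the
published competitor-trial means. The weights are conditional odds of
enrolment in the competitor study under a logistic trial-assignment model.
Its coefficients cannot be estimated by maximum likelihood — there is no
competitor IPD — so they are estimated by a method of moments: with
$z^*_i = z_i - \theta_z$ the effect modifiers centered on the published
means, minimize the convex objective

\[
Q(\alpha) = \sum_{i=1}^n \exp(z^*_i \alpha),
\qquad
\hat w_i = \exp(z^*_i \hat\alpha).
\]

The gradient of $Q$ is $\sum_i \hat w_i z^*_i$, so a stationary point is
exactly the moment condition: weighted effect-modifier means equal the
targets. The intercept is deliberately not estimated; weights are only
defined up to proportionality and every downstream quantity used here
(weighted means, contrasts, the effective sample size) is invariant to a
positive rescaling. A finite minimizer exists only when every centered
column changes sign somewhere; `check_feasibility()` detects the
degenerate case (all observed values of a covariate strictly on one side
of its target) before optimization, and `fit_trial_weights()` raises a
classed separation error instead of letting the optimizer diverge.

Numerically, `fit_trial_weights()` runs BFGS with the analytic gradient
from a zero start (initialization affects only the iteration count, the
problem being convex), then applies a few Newton steps with the analytic
Hessian $\sum_i \hat w_i z^{*\top}_i z^*_i$. Convergence is declared when
the relative gradient norm — identical to the largest absolute balance gap
on the centered scale — falls below $10^{-8}$; in practice the polish
leaves gaps near $10^{-12}$, comfortably inside the $10^{-6}$ balance the
package's tests assert.

The marginal A-vs-C effect in the competitor population is then the
contrast of weighted arm means, $g(\hat\mu_1) - g(\hat\mu_0)$, with $g$
the identity for mean differences or the logit/log for binary-outcome
scales; equivalently (and exactly, for the identity link) the treatment
coefficient of a weighted regression of outcome on treatment alone.

## The second stage (2SMAIC)

Even in a randomized index trial, any particular randomization leaves
chance imbalances in prognostic covariates between arms, and those
imbalances inflate the variance of the marginal estimate — increasingly so
at the small sample sizes typical of MAIC applications. The two-stage
estimator additionally fits an ordinary propensity-score logistic
regression of treatment on the baseline covariates *within* the index
trial and rescales the trial-assignment weights by the inverse estimated
probability of the treatment actually received:

\[
\hat\omega_i = \frac{t_i \hat w_i}{\hat e_i}
             + \frac{(1-t_i)\,\hat w_i}{1-\hat e_i}.
\]

The combined weights balance effect modifiers across trials and covariates
across arms. When the estimated propensity scores are constant (an
intercept-only model under a 1:1 split gives $\hat e_i \equiv 1/2$) the
combined weights are exactly twice the trial weights and the two-stage
estimator collapses onto one-stage MAIC — a reduction the test suite
checks. The same mechanism makes 2SMAIC applicable when the index study is
observational, with the propensity model then doing confounding control,
although the simulation engine below deliberately only generates
randomized trials.

## Truncation

Poor overlap between the trials' covariate distributions produces extreme
weights and a small effective sample size
$\mathrm{ESS} = (\sum_i w_i)^2 / \sum_i w_i^2$. `truncate_weights()`
implements the simplest stabilizer: every weight above the 95th percentile
of the pooled weight vector is set to that percentile. The percentile is
computed by linear interpolation (R's default type-7 quantile) on all
subjects pooled across arms; the cutpoint is a tuning constant, not an
estimate, and the package leaves it exposed as an argument. Truncation
deliberately sacrifices the moment condition — balance gaps reopen — so it
buys precision at the price of bias; it is applied to the one-stage
weights for T-MAIC and to the *combined* weights (after combination) for
T-2SMAIC. Note that truncation does not necessarily increase the ESS, and
nothing in the package assumes it does.

## Inference

All four estimators use the ordinary non-parametric bootstrap: index-trial
rows are resampled with replacement (the competitor evidence cannot be
resampled — there is no IPD), and every resample re-estimates the
trial-assignment model and, for the two-stage methods, the propensity
model, so the uncertainty of the weight estimation is propagated. The
point estimate is the mean over resamples and the variance the squared SD
over resamples (2,000 resamples in the full protocol); the original-sample
point estimate is available via `point_estimate = "original"`. The A-vs-B
interval is Wald normal on the summed variances. Resampling is simple
(unstratified) row resampling by default, the closest reading of the
protocol; arm-stratified resampling sits behind a flag. A resample that
itself hits separation or a degenerate fit is redrawn, with the redraw
count reported (`n_redrawn`) so fragile datasets are visible; estimation
aborts if resampling keeps failing (more than ninefold oversampling).
Percentile intervals and the small-ESS t-interval alternative are out of
scope.

Within the simulation engine, one bootstrap loop per replicate evaluates
all four methods on the *same* resamples (each resample fits the trial
model and the propensity model once and derives the four weight sets).
Each method's bootstrap distribution is identical to what separate loops
would produce; sharing resamples only removes redundant refits and makes
the methods' Monte Carlo errors positively correlated, which sharpens
paired comparisons such as the MSE orderings.

## The simulation engine

`sim_trial()` generates what the performance study needs and nothing more:
three covariates from a multivariate normal with common mean, SD 0.4 and
pairwise correlation 0.2, a fixed exact 1:1 allocation in randomized order
(a Bernoulli mode exists behind a flag; the fixed split is the direct
reading of a 1:1 allocation ratio), and continuous outcomes from

\[
y_i = \beta_0 + x_i\beta_1 + (\beta_t + x_i\beta_2)\,\mathbb{1}(t_i = 1) + \varepsilon_i,
\]

with intercept 5, prognostic coefficients 2, interaction coefficients 1,
treatment coefficient $-2$ and standard normal errors. Every covariate is
both prognostic and an effect modifier, and both active treatments share
the interaction coefficients, so in a population with covariate means 0.6
the true A-vs-C and B-vs-C effects are each $-2 + 3 \times 0.6 = -0.2$ and
the A-vs-B estimand is exactly zero; mean differences are collapsible, so
marginal and conditional truths coincide (`true_effects()`).

The factorial grid (`scenario_grid()`) crosses index-trial sizes
$n \in \{140, 200\}$ with index covariate means $\{0.5, 0.4, 0.3\}$ —
strong, moderate and poor overlap against the competitor mean 0.6. The
competitor trial always has 300 subjects at mean 0.6 and is re-simulated
in every replicate, then immediately reduced by `aggregate_ald()` to
realized covariate sample means plus the unadjusted OLS mean difference
and its nominal variance: estimators never see competitor IPD, by
construction. No trial-assignment mechanism is simulated — the two samples
are drawn independently from their stated covariate distributions, since
no formal process assigns subjects to one study or the other.

Per replicate, all four methods share the identical B-vs-C estimate, so
performance differences are attributable to the A-vs-C stage alone. A
replicate whose *original* index sample is infeasible is discarded (not
redrawn) and counted — at the full study size roughly one replicate in
several thousand in the worst cell — while bootstrap-level failures inside
a kept replicate are redrawn. Reproducibility uses a deterministic seed
tree: `(base_seed, scenario_id, replicate_id)` fixes each replicate's
stream, and the bootstrap consumes that stream, so any replicate can be
regenerated in isolation.

A note on reporting conventions: with the A-vs-B contrast computed as
$\hat\Delta_{AC} - \hat\Delta_{BC}$ and interactions that weaken treatment
at higher covariate values, truncation (which leaves the weighted
covariate means short of the competitor targets) drags the A-vs-C estimate
toward the index population's more negative effect, so the truncation-induced
bias is negative under this convention; flipping the direction of the
contrast flips every bias sign while leaving magnitudes, ESE, MSE and
coverage untouched. Comparisons of bias across conventions should
therefore be made in magnitude.

## Performance measures

`summarize_performance()` computes, per scenario and method, over the
replicates with `status == "ok"`: bias (mean estimate minus truth; MCSE
$\mathrm{SD}/\sqrt{N}$), empirical SE (sample SD, $N-1$ divisor; MCSE
$\mathrm{ESE}/\sqrt{2(N-1)}$), MSE (mean squared deviation; MCSE the SD of
the squared deviations over $\sqrt{N}$) and empirical coverage of the
nominal 95% Wald intervals (MCSE $\sqrt{p(1-p)/N}$), with $N$ always the
effective (non-discarded) replicate count. The identity
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{ESE}^2 (N-1)/N$ is asserted in
the tests with the divisor correction made explicit. `coverage_band()`
gives the Monte Carlo significance band around a nominal rate — at 5,000
replicates, 0.944 to 0.956 around 0.95.

## Problem sizes and what the checks show

The package's own validation runs the grid at a *scaled* size — 500
replicates and 200 bootstrap resamples per replicate (`scenario_grid("scaled")`)
— and compares each checked cell with the full-scale study values within
three Monte Carlo SEs of the scaled run; `scripts/acceptance.R` re-runs
four scenario cells the same way. At this size the bias MCSE in the worst
cell is about 0.034 and the coverage MCSE about 0.013, so these are
consistency checks, not precision replication. Scaling down the bootstrap
from 2,000 to 200 resamples leaves point estimates unbiased and inflates
the ESE only through the $V_{boot}/B$ term (well under 1% here), but makes
individual variance estimates noisier.

The generator emulates exactly the stated study conditions: normal
covariates with a single common correlation, linear and additive outcome
effects, perfectly shared effect modification between A and B, no missing
data, no non-adherence. Passing tests therefore demonstrate correctness of
the estimators under these conditions; they say nothing about performance
under non-normal covariates, higher-order effect modification (where means
balancing is insufficient), unmeasured effect modifiers, or observational
index studies — all of which the estimators accept as inputs but the study
design does not probe.

## Known limitations

* Only anchored comparisons: both stages presuppose the common comparator;
  the two-stage construction is undefined for single-arm (unanchored)
  contrasts.
* Sandwich variance estimation is not provided; inference is bootstrap
  only.
* Only first moments are balanced. Published variances or correlations of
  the competitor covariates are ignored by design.
* Binary-outcome links are provided for the estimators, but the simulation
  engine generates continuous outcomes only.
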