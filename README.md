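# maic2s

Anchored population-adjusted indirect treatment comparisons for the
standard evidence situation in health technology assessment: treatment A
was compared with a common comparator C in a trial with individual patient
data (IPD), treatment B was compared with C in a trial available only as
published aggregate-level data (ALD), and the question is the marginal
A-vs-B effect in the competitor trial's population,

    Δ̂_AB = Δ̂_AC − Δ̂_BC,    V̂(Δ̂_AB) = V̂(Δ̂_AC) + V̂(Δ̂_BC).

The package is for HTA statisticians and methods researchers. It
implements four weighting estimators of the transported A-vs-C effect and
a simulation engine for benchmarking them:

* **MAIC** — matching-adjusted indirect comparison: trial-assignment odds
  weights `w_i = exp(z*_i α̂)` estimated by a method of moments (minimizing
  the convex objective `Q(α) = Σ_i exp(z*_i α)` over effect modifiers
  centered on the published means), so weighted effect-modifier means hit
  the competitor targets exactly.
* **2SMAIC** — a second stage fits a propensity-score logistic regression
  of treatment on the baseline covariates within the index trial and
  rescales the odds weights by the inverse probability of the treatment
  received, `ω̂_i = t_i w_i/ê_i + (1−t_i) w_i/(1−ê_i)`, correcting chance
  between-arm imbalances in prognostic covariates and improving precision.
* **T-MAIC / T-2SMAIC** — either weight set with all weights above their
  pooled 95th percentile capped at that percentile, trading bias for
  stability when overlap is poor.

Inference is by the ordinary non-parametric bootstrap (weights re-estimated
in every resample); intervals are Wald normal on the summed variances.
Diagnostics include the effective sample size `(Σw)²/Σw²`, balance tables
and weight-distribution plots. The simulation engine reproduces a
six-scenario factorial study (index-trial n ∈ {140, 200} × strong/
moderate/poor covariate overlap) with bias, empirical SE, MSE and coverage
summaries, each with Monte Carlo standard errors.

## Worked example

```r
library(maic2s)
set.seed(42)
coef <- dgm_coefficients()
index <- sim_trial(140, 0.4, coef)                 # A-vs-C trial with IPD
ald <- aggregate_ald(sim_trial(300, 0.6, coef))    # published B-vs-C summaries

tw <- fit_trial_weights(index, c("x1", "x2", "x3"), ald)
tw
#> <trial_weight_fit>
#>   alpha: x1=0.8343, x2=1.0047, x3=0.7547
#>   n = 140, ESS after weighting = 77.5
#>   objective = 104.829, balance gap = 3.23e-14

balance_table(index, trial_weight_set(tw), c("x1", "x2", "x3"), ald)
#> # A tibble: 3 × 5
#>   covariate unweighted_mean weighted_mean target      gap
#> 1 x1                  0.397         0.631  0.631 3.24e-14
#> 2 x2                  0.416         0.636  0.636 4.44e-15
#> 3 x3                  0.400         0.598  0.598 3.33e-15

ac <- maic(index, ald, c("x1", "x2", "x3"), method = "2SMAIC",
           n_boot = 1000, seed = 1)
indirect_comparison(ac, ald)
#> <indirect_comparison: A vs B via common comparator, 2SMAIC>
#>   estimate -0.1035 (mean_difference), 95% CI [-1.3308, 1.1238]
```

The weighted effect-modifier means match the published competitor means to
machine precision (the `gap` column), at the cost of shrinking the
effective sample size from 140 to about 78. The two-stage A-vs-C estimate
(−0.367, bootstrap SE 0.564) combines with the published B-vs-C estimate
into an A-vs-B mean difference of −0.10 whose confidence interval
comfortably includes zero — as it should here, since both simulated
treatments were generated with identical effects.

User data go through the same functions (`read_ipd()`, `read_ald()`,
`run_analysis()`), or the thin command-line wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "maic2s.R", package = "maic2s"))')" \
  analyze --ipd ipd.csv --ald ald.json --effect-modifiers x1,x2,x3 \
  --boot 2000 --seed 1 --out results/
Rscript .../maic2s.R simulate --preset scaled --seed 1 --out sim_out/
```

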