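# acwrbayes

Bayesian analysis of session-RPE training load and injury risk in team
sports.

## The problem

Team-sport practitioners monitor internal training load with the session
rating of perceived exertion (sRPE): each session contributes
`duration (min) × RPE (Borg CR-10)` arbitrary units (AU), summed into a
weekly **acute load** (AL). The **acute:chronic workload ratio**

```
ACWR_t = AL_t / chronic_t ,   chronic_t = mean(AL_{t-3}, ..., AL_t)
```

is widely used as an injury-risk flag, on the theory that a spike of
recent load above the level a player is adapted to predicts injury. That
theory is contested: because the denominator is a slowly varying average,
the ACWR may be little more than a rescaled acute load. `acwrbayes`
implements the analysis needed to test this claim on a squad's season of
session logs:

* **Load metrics** — weekly acute, cumulative (2–4 wk) and chronic loads,
  coupled or uncoupled ACWR, training monotony, and **ACWRr**, a null
  comparator in which the chronic denominator is replaced by a random
  draw `γ ~ Normal(1900, 730²)` AU, destroying all individual
  chronic-load information while keeping the marginal scale.
* **Robust group comparison** — a BEST-style Bayesian Student-t model
  `y ~ t(ν, μ_g, σ_g)` comparing a metric between injured and
  non-injured player-weeks, with posterior mean difference
  `μ_inj − μ_not` and effect size `(μ_inj − μ_not) / sqrt((σ²_inj + σ²_not)/2)`.
* **Quantile injury GLM** — a Bayesian logistic model
  `injured ~ Bernoulli(logit⁻¹(β₀ + β_q))` over quartiles q of a load
  metric, with sum-to-zero deviation coding (`Σ β_q = 0` for every
  posterior draw) and a hierarchical shrinkage prior on the deviations;
  conditional injury probabilities `P(inj | q) = logit⁻¹(β₀ + β_q)` are
  derived draw-wise.
* **Posterior machinery** — MCMC via JAGS, 95% highest-density intervals
  (sorted-window), split-R̂ and effective sample size with Geyer's
  initial-positive-sequence truncation.
* **Synthetic team season** — a calibrated generator (35 players, 12
  followed 52 weeks and 23 followed 26 weeks, ≈815 complete player-week
  observations, ≈30 time-loss injuries) with null and load-dependent
  injury processes, so the whole pipeline is testable end to end.

If the ACWR carries real information about a player's dynamic state, it
should beat ACWRr at predicting injury; if the two models give
indistinguishable injury probabilities, the ratio adds nothing over
acute load.

## Worked example

The quartile injury contingency of a 35-player elite-soccer cohort (815
player-weeks, 30 time-loss injuries), by ACWR quartile, is a sufficient
statistic for the GLM:

```r
library(acwrbayes)

tab <- tibble::tibble(
  quantile    = 1:4,
  injured     = c(3L, 6L, 5L, 16L),
  not_injured = c(202L, 213L, 182L, 188L)
)
fit <- fit_quantile_glm(tab, seed = 1, metric = "acwr")
fit
#> Bayesian quantile injury GLM (acwr): 30 injuries / 815 rows in 4 quartiles
#>   term     mean   hdi_low hdi_high   ess  psrf
#>  beta0 -3.42914 -3.860605 -3.01383 13742 1.001
#>  beta1 -0.56370 -1.392420  0.16332  8362 1.000
#>  beta2 -0.12376 -0.751662  0.51373 22616 1.000
#>  beta3 -0.14259 -0.823859  0.50659 21953 1.000
#>  beta4  0.83006  0.183712  1.45620  5612 1.002
#>   p_q1  0.02033  0.004238  0.03910  8165 1.001
#>   p_q2  0.02969  0.010477  0.05057 20880 1.000
#>   p_q3  0.02942  0.009196  0.05131 19766 1.000
#>   p_q4  0.07149  0.036868  0.10919 10347 1.001

conditional_injury_probability(fit, 4)
#> # A tibble: 1 × 6
#>   term    mean hdi_low hdi_high    ess  psrf
#> 1 p_q4  0.0715  0.0369    0.109 10347.  1.00
```

Read: the baseline log-odds of injury in the following week is
β₀ ≈ −3.43; only the top ACWR quartile deviates credibly from baseline
(β₄ ≈ 0.83, 95% HDI excluding 0), and a player-week in that quartile
carries a ≈ 7% posterior probability of injury in the next week (95%
HDI 0.04–0.11). Every row reports convergence diagnostics (split-R̂,
ESS).

A full synthetic-season run — metrics, descriptive tables, robust
comparisons, both GLMs, and a manifest — is one call:

```r
cfg <- pipeline_config(
  synthetic = synthetic_config(seed = 42),
  seed = 42, out_dir = "results/run1"
)
res <- run_pipeline(cfg)
```

`tidy()`, `glance()` and `autoplot()` methods are provided for the
fitted objects.

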