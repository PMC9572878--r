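---
title: "Methods: Bayesian workload-injury analysis with acwrbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian workload-injury analysis with acwrbayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`acwrbayes`, in the spirit of a methods section: what is computed, under
which assumptions, with which defaults, and where the edges are.

## 1. Load metrics

**Session load.** Internal load of one session is `duration_min × rpe`
in arbitrary units (AU), with RPE on the Borg CR-10 scale. We accept the
scale endpoints 0 and 10 and half-point ratings; durations must be
non-negative. The operation is bilinear, which the tests exploit.

**Weekly aggregation.** Acute load (AL) is the sum of session loads over
one calendar week. Cumulative loads over 2–4 trailing weeks are sums of
weekly ALs; chronic load is the 4-week rolling *mean* of weekly ALs.
Numerator and denominator of the ACWR are therefore on the same weekly
scale, so a constant training program gives ACWR = 1 exactly.

**Coupled vs uncoupled.** By default the chronic window *includes* the
current week (coupled convention, `ACWR_t = AL_t / mean(AL_{t-3..t})`).
`weekly_loads(coupled = FALSE)` switches to the uncoupled convention
(window `t-4..t-1`). The coupled default matches the reading of the
chronic load as "the moving average of the last four weeks" with the
current week counted; it bounds the coupled ACWR within [0, 4].

**Calendar grid and exclusions.** Metrics are computed on each player's
full calendar-week grid. A week without any recorded session (absence
after a time-loss injury, unrecorded week) is not turned into a zero-load
row — zero load would be a statement about training that did not happen —
and it invalidates every 4-week window that covers it. Observation rows
are exactly the trained weeks with a complete 4-week history. This is the
mechanism by which a nominal squad-season of ~1,200 player-weeks reduces
to roughly 815 usable observations, and `run_pipeline()` logs the
reduction so it can be audited.

**Monotony.** Weekly mean daily load divided by the SD of the daily
loads. Daily loads are the 7 calendar-day totals with rest days counted
as 0 AU; the sample SD (n−1) is used, as is conventional when nothing
else is specified. Constant daily load makes the index undefined
(signalled, and reported as NA in tables) rather than infinite.

**ACWRr — the null comparator.** For each observation row the chronic
denominator is replaced by an independent draw
`γ ~ Normal(1900, 730²)` AU. The mean is the squad-scale chronic load;
730 AU is interpreted as the *standard deviation* of the denominator (a
variance of 730 AU² would make the denominator essentially constant at
1900 ± 27 AU, i.e. a rescaled acute load rather than a noisy one, and
would be inconsistent with an ACWRr interquartile range roughly twice as
wide as the ACWR's). Draws at or below a positivity floor (default 50
AU) are rejected and redrawn: without a floor, near-zero and negative
denominators produce sign flips and unbounded ratios that have no
workload interpretation. γ is drawn once per observation; the seed is a
required argument, so the metric is reproducible.

**Quartile discretisation.** Because ACWR and ACWRr live on different
scales, both (and acute load) are discretised into quartile groups of
the pooled observation rows. Cut points are the 25th/50th/75th empirical
percentiles with the linear-interpolation convention; assignment is
upper-inclusive (a value equal to a cut point goes to the lower group).
On tie-free data the four groups differ by at most one row; ties at a
cut point can make groups visibly unequal, which is why equality of
group sizes is never asserted on realistic data.

## 2. Robust two-group comparison

To compare a load metric between injured and non-injured player-weeks we
use a BEST-style robust model rather than a t-test: load data are
symmetric but heavy-tailed, and a Normal likelihood would inflate the
scale estimate and can bias the location. A Shapiro–Wilk check per group
is computed and reported as motivation, but never changes the model.

The likelihood is `y_gi ~ StudentT(ν, μ_g, σ_g)` with group-specific
location and scale and a single shared degrees-of-freedom parameter ν
(one normality parameter per comparison, which is also what one number
per comparison in a results table implies). Priors are the standard BEST
defaults, deliberately vague relative to the data:

* `μ_g ~ Normal(pooled mean, (1000 × pooled SD)²)`
* `σ_g ~ Uniform(pooled SD / 1000, pooled SD × 1000)`
* `ν ~ 1 + Exponential(mean 29)` — mass spread over both near-Normal
  (ν > 30) and heavy-tailed regimes.

Derived quantities are computed draw-wise: `mean_diff = μ_inj − μ_not`
and `effect_size = mean_diff / sqrt((σ²_inj + σ²_not)/2)`. Swapping the
group labels negates both exactly, draw for draw; the effect size is
invariant to a common affine rescaling of the data. A difference is
declared *credible* iff its 95% HDI strictly excludes zero (no ROPE; an
interval touching zero is not credible).

The observation unit is the player-week, and rows are treated as
exchangeable within group. Repeated measures of the same player are
*not* modelled; this replicates the analysis the package is built
around and is a known limitation (a mixed-effects extension is out of
scope).

## 3. Quantile injury GLM

Injury in the following week is modelled as
`injured_i ~ Bernoulli(logit⁻¹(β₀ + β_{q(i)}))`, with q(i) the quartile
of the chosen metric for the predictor week — the completed week
immediately preceding onset. Aggregating rows within quartile gives the
likelihood-equivalent Binomial form; `fit_quantile_glm()` accepts either
and aggregates internally, so the two input forms yield identical
posteriors under the same seed. An injury occurring before the player
has a complete 4-week history has no predictor row; it is dropped with a
warning.

**Coding.** The deviations β₁..β₄ are sum-to-zero: β₀ is the mean of
the four per-quartile logits and each β_q the deviation from it. We
sample a redundant parameterisation (free intercept `a0` plus free
effects `a_q`) and sweep the category mean into the intercept after
sampling (`β₀ = a0 + ā`, `β_q = a_q − ā`). The constraint then holds at
machine precision for every draw, and the redundant parameterisation
mixes well; `a0` and `ā` are individually non-identified by design, so
convergence is gated on the reported swept parameters.

**Priors.** `β₀ ~ Normal(0, 2²)` on the logit scale — weakly
informative, covering baseline weekly injury probabilities from below
0.002 to above 0.5. Deviations get a hierarchical prior
`a_q ~ Normal(0, σ_β²)`, `σ_β ~ half-Cauchy(0, 2.5)`: with only four
groups the group-level scale is poorly identified and the half-Cauchy
with a moderate scale is the canonical weakly-informative choice; 2.5 is
the familiar default scale for logistic-regression coefficients. The
hierarchy induces mild shrinkage of the deviations toward zero relative
to the plug-in empirical logits, which is the behaviour expected of a
Bayesian "logistic ANOVA". Both scales are exposed in `glm_priors()`,
including a non-hierarchical flat-prior mode used by the tests to check
convergence to empirical proportions at large counts.

**Derived quantities.** `P(inj | q) = logit⁻¹(β₀ + β_q)` per draw.
`compare_metrics()` takes the draw-wise difference of the fourth-quartile
probability between two fitted models (paired by draw index, truncating
to the shorter set if they differ) and declares the metrics "similar"
iff the difference's 95% HDI contains zero. Quartile thresholds quoted
in reports (e.g. "ACWR > ...") are recomputed from the fitted binning of
the data at hand, never hard-coded.

## 4. Posterior machinery

Sampling is delegated to JAGS through `rjags` — the appropriate tool for
these conditionally conjugate models — behind `sample_posterior()`,
which fixes the reproducibility contract: per-chain Mersenne-Twister
seeds derived deterministically from one integer seed, so identical
seeds give identical draws. Defaults are 4 chains × 10,000 retained
iterations after 2,000 warmup (plus 1,000 adaptation), which yields
effective sample sizes in the 10³–10⁴ range for these models.

The diagnostics are implemented in the package:

* **HDI** by the sorted-window method: the narrowest window spanning
  `⌈0.95 n⌉` sorted draws. No density estimation is involved; for
  unimodal symmetric posteriors it agrees with the central interval up
  to Monte-Carlo error, and it is monotone in the mass.
* **split-R̂**: each chain is halved and the Gelman–Rubin statistic
  computed on the split chains — the stricter modern default, sensitive
  to trending chains. All-equal chains return 1.
* **ESS** as `n / (1 + 2 Σ ρ_k)` with Geyer's initial-positive-sequence
  truncation of the autocorrelation sum (FFT-based autocovariance);
  per-chain values are summed for multi-chain summaries.

Fits gate on split-R̂ < 1.01 for every reported parameter; a failed gate
signals a diagnostics condition that carries the partial draws and the
diagnostics table, so callers can inspect or (in simulation loops)
discard that replicate. ESS is always reported; `sample_posterior()`
can additionally gate on a minimum ESS (default 400) for users who want
a hard floor.

## 5. The synthetic team season

The generator emulates the cohort structure the analysis assumes: 35
players (12 followed for 52 weeks, 23 for 26 weeks), 5–7 sessions per
week, session duration ~ Normal(70, 15²) min, RPE ~ Normal(4.3, 1.5²)
rounded to half points and clipped to [1, 10]. Training periodisation is
represented by a player-week log-load multiplier following an AR(1)
process (coefficient 0.6, stationary SD 0.30) plus a persistent
between-player level (SD 0.08); a player-week is unrecorded with
probability 0.04. These defaults were calibrated once so that the pooled
weekly acute load has median near 1800 AU with IQR near (1400, 2308) AU
and the observation table holds roughly 815 complete rows — the scale of
the reference cohort — and the calibration is asserted by the test
suite.

Injuries are drawn per observation row with
`logit(p) = logit(0.037) + effect × (q − 2.5)`, where q is the acute or
ACWR quartile under the load-dependent models and the effect term is
absent under the null model (baseline 0.037 ≈ 30/815 injuries per
player-week). Time loss is log-normal with median 10 days; the player is
absent (sessions removed, no new onset possible) until return. At most
one injury can be open per player.

What the generator does *not* emulate: match-congestion calendars and
microcycle structure beyond AR(1) smoothness, positional or
between-player differences in injury hazard (heterogeneity is off by
default), injury severity gradation, and any external-load (GPS)
channel. Tests passing on synthetic data therefore validate the
*pipeline* — metric arithmetic, model correctness, calibration of
uncertainty — not the epidemiology of any real squad.

## 6. Numerical choices and degenerate inputs

* Undefined quantities (chronic load with < 4 weeks of history, ACWR
  with non-positive chronic load, monotony with zero SD) raise typed
  conditions in the scalar API and become NA/excluded rows in the
  table-building API.
* The ACWRr rejection floor (50 AU) is configurable; with
  `denominator_sd → 0` the metric converges to `acute / 1900`
  deterministically, which the tests check.
* Quartile ties are broken upper-inclusively; with fewer than four
  distinct values the table builder emits NA labels with a warning
  rather than failing the whole build.
* Robust-fit initial values are the group means/SDs and ν = 30, keeping
  early adaptation away from the heavy-tail regime.
* Report tables round to 2 decimals (counts and percentages to
  integers); draw-level exports keep full precision.
* Validation problem sizes are chosen to keep the suite quick while
  leaving Monte-Carlo noise well below the tolerances: coverage of the
  robust model uses 50 replicates at group sizes (30, 785) with 2
  chains × 1,500 retained iterations; the null-structure check uses 50
  simulated seasons; conjugate-oracle checks compare posterior means
  within 3 Monte-Carlo standard errors.

## 7. Interface

The package is R-native and pipe-friendly: every user-facing function
takes a data frame first and returns a tibble, fitted objects have
`tidy()`, `glance()` and `autoplot()` methods, and `run_pipeline()`
orchestrates the full sequence (ingest/simulate → metrics → descriptive
tables → robust comparisons → GLMs → metric comparison → diagnostics →
manifest) with stage-level logging and a deterministic manifest. The
exported functions and this vignette are the intended entry points;
`scripts/acceptance.R` shows the headline computation as a script.
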