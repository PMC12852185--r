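---
title: "Colony census trends: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony census trends: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrend)
```

# The model

Every colony is assumed to follow a discrete-time, density-independent
exponential trajectory with multiplicative observation error:

$$N_t = N_0\,\lambda^{(t - t_0)}\,\varepsilon_t, \qquad
  \ln \varepsilon_t \sim N(0, \sigma^2),$$

where $N_t$ is the count of breeding pairs in season $t$, $\lambda$ the
finite rate of increase and $r = \ln\lambda$ the instantaneous rate. Taking
logs makes the error additive and the trajectory linear, so for colonies with
three or more censuses $r$ is the OLS slope of $\ln N_t$ on $t$
(`fit_log_linear()`), and its squared standard error is the sampling variance
$v_t$ used downstream. With exactly two censuses the model is saturated and
$\lambda = (N_t/N_0)^{1/(t-t_0)}$ directly (`fit_two_point()`); the two
estimators coincide exactly on two points. Single-record colonies support no
trend and are excluded by `fit_trends()`.

Assumptions worth keeping in mind: no density dependence, no demographic
(process) stochasticity, independent lognormal errors with constant variance,
and one count per breeding season. A season spanning two calendar years
("1989–1990") is keyed to its **first** calendar year, which is what makes the
Malvinas/Falklands censuses 30 seasons apart and its 1996 interpolation land
on the published value.

Zero counts are rejected, not offset: $\ln 0$ is undefined and a silent
$+1$ would bias small colonies. Callers who believe a zero is a true
extinction event need a different model.

# Bootstrap confidence intervals

Intervals for $\lambda$ come from resampling the residuals of the log-linear
fit (`bootstrap_ci()`): residuals are leverage-adjusted
($e_i/\sqrt{1-h_{ii}}$) and re-centered — the standard recipe that restores
their variance to the error variance — then resampled with replacement, added
back to the fitted log-values, and the slope re-estimated per replicate; the
interval is the percentile interval of the replicate $e^{\hat r}$ values.
Defaults: 2,000 replicates, 95% level, and a **mandatory seed** in the
API — there is no hidden global RNG state, and a fixed seed gives
bit-identical intervals.

Percentile intervals on very short series are anti-conservative, and users
should know by how much. The bootstrap slope distribution is approximately
normal with a residual-based scale, while the honest sampling distribution of
the studentized slope has $n-2$ degrees of freedom; the effective coverage of
a nominal 95% interval is therefore about $P(|t_{n-2}| \le 1.96)$: roughly
0.86 at $n = 5$, 0.88 at $n = 6$, 0.93 at $n = 20$. The test suite checks
coverage against exactly this reference rather than pretending the nominal
level is achieved. Raw-residual resampling (`residual_type = "raw"`) is
available for comparison and is strictly worse at small $n$.

Trend classification is CI-centric, matching how such tables are reported:
`positive_significant` when the lower bound exceeds 1,
`negative_significant` when the upper bound is below 1, `stable` when the
interval contains 1 (a point category $\lambda = 1$ has measure zero
otherwise). Two-point fits have no interval; they are classified by the sign
of $r$ and flagged `*_unsupported`.

# Aggregation

Two pooling schemes, deliberately simple and moment-based (no hierarchical
MCMC):

**Simple weighting** (`aggregate_simple()`): $r_{general} = \sum r_i w_i /
\sum w_i$ with $w_i = \bar N_i Y_i$, usable for every colony with at least
two records. No interval recipe is inherent to this estimator, so the
package's choice is a nonparametric bootstrap over colonies (resample
colonies with replacement, recompute the weighted mean; 1,000 replicates,
percentile, seeded) — it treats the colony set as the sampling unit, which is
the variability that matters when pooling heterogeneous sites.

**Empirical-Bayes shrinkage** (`eb_shrink()` + `aggregate_eb()`), restricted
to colonies with a trend variance (≥ 3 records):

$$\tau^2 = \max(V_t - \bar v_t,\, 0), \qquad
  w_{tb} = \frac{v_t}{v_t + \tau^2}, \qquad
  t_b = \bar t\, w_{tb} + t\,(1 - w_{tb}), \qquad
  v_{tb} = w_{tb}\,\tau^2,$$

pooled as $r_{general} = \sum w^A t_b$ with abundance weights $w^A_i =
\frac{1}{T_i}\sum_{t \in T_i} C_{i,t} / \sum_j C_{j,t}$, renormalized to sum
to one. Choices made where the method statement is open:

* $\tau^2$ is truncated at zero (the raw moment difference can go negative);
  this is standard method-of-moments practice and keeps $w_{tb} \in [0,1]$.
  At $\tau^2 = 0$ every trend collapses to the mean, and a colony with
  $v_t = 0$ is never shrunk — both limits fall out of the formulas.
* $V_t$ uses the sample ($n-1$) denominator; $\bar t$ is the unweighted mean
  of colony trends.
* The pooled variance is the weighted mean of the shrunk variances,
  $\sum w^A v_{tb}$, mirroring the trend formula; the source prints the same
  right-hand side for both the pooled trend and its variance, which can only
  be a typo. The alternative $\sum (w^A)^2 v_{tb}$ (variance of the weighted
  mean under independence) is available via `variance = "weighted_sq"`.
* The denominator of a year's abundance share sums only colonies **observed**
  in that year: unobserved counts are unknown, not zero.

Both aggregates are convex combinations of the colony rates, agree exactly
when all colonies share one rate, and respond monotonically to weights —
these are tested properties, not hopes.

# Interpolation and projection

`interpolate_to_year()` evaluates the fitted exponential anchored at the
**latest census at or before the target year**: an observed year returns the
observed count exactly, and anchoring near the target limits compounding
error. Years before a colony's first census are refused
(`excluded_backward`, contributing zero to totals but always flagged) —
backward extrapolation of an exponential is exactly the unsupported
overestimation the guard exists to prevent; `allow_backward = TRUE` exists
for testing. `project_to_year()` compounds forward from the most recent
census.

Colonies still in their explosive colonization phase make full-series rates
meaningless for projection; `recent_lambda()` refits the last `window`
records (default 3 — the smallest window that still allows a regression fit,
appropriate for colonies whose recent counts have plateaued). In
`national_summary()` the recent-phase rate replaces the full-series one for
target years from 2016 onward (configurable), matching the interpolation
years those refits are meant for. Strata (2-record vs ≥ 3-record) are derived
from the data, never hard-coded; totals are reported with and without the
Malvinas/Falklands unit because that single colony dominates any historical
total it enters. Abundances stay fractional internally; rounding (nearest
pair, integer percent) happens only at report time.

# Plot-based field estimation

`estimate_colony_abundance()` expands mean plot density to colony area:
$\hat N = \bar c / a \cdot A$ for plot counts $c$ of active nests (an adult
or a pair with eggs), plot area $a$ and colony area $A$. The plot area
defaults to the geometric $\pi (5.65\,\mathrm{m})^2 = 100.29\,\mathrm{m}^2$
rather than the nominal 100 m² (a flag forces the nominal value; the two
differ by 0.3%). This is a deliberate simplification of spatial (natural
neighbor) interpolation of plot densities, which needs plot coordinates and
GIS machinery orthogonal to the trend pipeline; the estimator is unbiased
under uniform random plot placement on a homogeneous nest field (verified by
Poisson simulation in the tests) but, unlike spatial interpolation, it cannot
capture density gradients within a colony. Results carry an
`estimator = "mean_density_expansion"` tag so downstream users know which
method produced them.

# The synthetic generator

`simulate_metapopulation()` generates datasets with the structure the
pipeline assumes, plus the ground truth needed to measure recovery. Defaults
are fixed once, as the study conditions the package emulates:

* **73 colonies** split 8 single-record / 33 two-record / 32 ≥ 3-record
  (largest-remainder allocation of the compiled dataset's stratification),
  with ≥ 3-record colonies drawing 3–8 censuses;
* true rates $r \sim N(0.01, 0.06)$ — a near-stable metapopulation whose
  tails span the published per-colony range (−0.32 to 0.56);
* initial sizes $10^{U(2,5)}$ pairs; census years on integers in 1985–2024;
* lognormal observation noise with $\sigma = 0.15$ — census repeatability
  for burrow-nesting seabirds is commonly in the 10–20% range, and 0.15 sits
  in the middle;
* optionally one dominant decliner: 1.3 million pairs falling at
  $r = -0.0855$ over two censuses 30 years apart, observed without error
  (its printed counts are point estimates, not a noisy series).

What it deliberately does **not** emulate: demographic/process noise,
density dependence, observer-specific bias, spatially correlated survey
effort, or dispersal between colonies. Passing recovery tests therefore shows
the estimators are correct **under the model's own assumptions**, not that
real censuses satisfy them.

`recovery_report()` summarizes bias, RMSE and CI coverage per stratum.
Verified properties (fixed seeds): noiseless data are recovered to machine
precision; $\hat r$ is unbiased within 3 Monte-Carlo standard errors; RMSE
falls with more census years at fixed span and noise; coverage matches the
$t$-oracle above; removing a dominant decliner raises the aggregate.

# Numerical and reproducibility choices

* All randomness is seeded explicitly; seeded helpers save and restore the
  caller's RNG state. `run_pipeline()` fans one run seed out to per-stage,
  per-colony seeds via a stable string hash (`derive_seed()`), so adding a
  stage or colony never perturbs the streams of earlier ones, and reruns are
  byte-identical.
* Census CSVs serialize counts with 17 significant digits, making the
  read/write round trip the identity on doubles.
* Percentile intervals use the default quantile definition (type 7); with
  ≥ 1,000 replicates the choice is immaterial at the scales reported.
* Degenerate inputs fail loudly: duplicate (colony, year) records, negative
  counts, zero counts in trend fits, identical census years, windows longer
  than the series, mismatched colony sets between trends and weights.

Test problem sizes were chosen to give stable Monte-Carlo verdicts at
interactive runtimes: 400–1,000 series for coverage checks (binomial SE
≈ 0.01–0.016), 1,500–10,000 colonies for bias (SE of the mean well below the
effect sizes of interest), 200–2,000 bootstrap replicates depending on the
test. The acceptance checks run the coverage suite at 1,000 series × 999
replicates and the recovery suite at 10,000 colonies.

# Known limitations

* The exponential model is blind to trend changes within a series; the
  recent-phase refit is a pragmatic patch for two known boom colonies, not a
  changepoint method.
* Two-point colonies contribute no uncertainty, so the simple aggregate's
  bootstrap understates total uncertainty where such colonies dominate.
* Percentile bootstrap intervals undercover at $n \le 6$ (see above);
  analysts needing calibrated small-sample intervals should use the
  $t$-reference or more censuses.
* Projected totals are point values; no uncertainty is propagated into
  abundance tables.
* The published per-colony table bundled for validation contains two rows
  (El Pedral, Isla Leones) whose printed $r$ and $\lambda$ disagree by
  slightly more than two-decimal rounding (gaps 0.0055 and 0.0053); they are
  transcribed as printed.
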