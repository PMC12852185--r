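# pentrend

Population trend estimation and abundance projection for Magellanic penguin
(*Spheniscus magellanicus*) breeding colonies along the Argentine coast — and
for any census dataset with the same shape: sparse, uneven time series of
breeding-pair counts per colony.

Colony monitoring data of this species are heterogeneous: a few colonies have
decades of annual censuses, many have two counts taken years apart, and some
have a single record. `pentrend` implements the full desk pipeline for such
data, for population ecologists and conservation analysts:

1. **Per-colony trends.** Each colony follows a discrete-time,
   density-independent exponential model with multiplicative observation
   error,

   N_t = N₀ · λ^(t − t₀),   r = ln(λ).

   Colonies with ≥ 3 censuses are fit by ordinary least squares of ln N_t on
   t (r is the slope, λ = e^r), with 95% confidence intervals from a
   residual bootstrap (percentile intervals, leverage-adjusted centered
   residuals, seeded). Colonies with exactly 2 censuses use the direct
   two-point estimator λ = (N_t/N₀)^(1/(t−t₀)), with no interval.
   Single-record colonies are excluded. Trends are classified as positive
   (λ > 1), negative (λ < 1) or stable, statistically supported by the CI
   where one exists.

2. **National aggregation.** Colony rates are pooled two ways: (a) a simple
   weighted mean with weights w_i = N̄_i · Y_i (mean abundance × census
   years), and (b) empirical-Bayes moment shrinkage — τ² = max(V_t − v̄_t, 0),
   w_tb = v_t/(v_t + τ²), t_b = t̄·w_tb + t·(1 − w_tb) — pooled with
   abundance weights w^A (each colony's mean share of the total counted
   population over its census years). λ_general = e^(r_general).

3. **Abundance interpolation and projection.** Colony abundances are
   evaluated at reference years (1996, 2006, 2016 by default) anchored at the
   latest census at or before the target year, never extrapolated backward
   before a colony's first record, and projected forward (2024) from the most
   recent census. Boom-phase colonies (El Pedral, Estancia San Lorenzo) can
   use a recent-phase λ refit on their latest records. Totals are stratified
   by data availability and reported with and without the Malvinas/Falklands
   unit.

4. **Field surveys and validation.** A circular-plot density-expansion
   estimator (5.65 m rope plots) for plot-count surveys; a transcription of
   the published 65-colony trend table (`load_table1()`) for validation; and
   a seeded synthetic-census generator with known ground truth
   (`simulate_metapopulation()`) for parameter-recovery studies.

## Worked example

The Malvinas/Falklands archipelago is treated as one analytical unit with two
usable censuses: about 1,300,000 breeding pairs in the 1989–1990 season and
about 100,000 in 2019–2020 (seasons are keyed to their first calendar year,
so the span is 30 years).

```r
library(pentrend)

im  <- colony_series("IM", c(1989, 2019), c(1300000, 100000),
                     name = "Islas Malvinas", region = "Malvinas")
fit <- fit_trend(im)
fit
#> <colony_trend> IM [two_point]
#>   r = -0.0855   lambda = 0.9181   (2 records, 30-yr span)
#>   classification: negative_unsupported
```

The unit lost about 8.2% of its breeding pairs per year. Interpolating and
projecting on that fitted trajectory:

```r
interpolate_to_year(im, fit, 1996)$abundance   # 714535 breeding pairs
project_to_year(im, fit, 2024)                 # 65214 breeding pairs
#> a ~91% decline over three decades
```

A colony with more temporal support gets a log-linear fit with a bootstrap
interval:

```r
s <- simulate_colony(0.05, 800, seq(2000, 2012, 3), noise_sd = 0.1,
                     colony_id = "ESL-like", seed = 42)
bootstrap_ci(s, n_boot = 2000, seed = 1)
#> <colony_trend> ESL-like [log_linear]
#>   r = 0.0475   lambda = 1.0487   (5 records, 12-yr span)
#>   95% CI for lambda: [1.0312, 1.0661] (residual bootstrap, 2000 reps)
#>   classification: positive_significant
```

`fit_trends()`, `aggregate_trends()` and `national_summary()` apply these
steps to a whole census collection; `run_pipeline()` chains everything into a
report bundle (CSVs, text report, YAML run configuration, log). A thin
command-line wrapper with `simulate` / `fit` / `aggregate` / `project` /
`plots` / `report` / `reproduce-published` subcommands is installed at
`system.file("scripts", "pentrend.R", package = "pentrend")`.

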