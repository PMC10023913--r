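# lagcausal

Short-term lagged **causal** effects of daily air-pollutant and
meteorological exposures on daily clinical visit counts — the
epidemiologist's question "if SO2 had been lower five days ago, how many
fewer asthma visits would we see today?", answered with an explicit causal
graph rather than a bare correlation.

The package is aimed at environmental-epidemiology analysts working with
date-indexed exposure panels (AQI, PM2.5, PM10, SO2, NO2, CO, O3 plus
temperature, humidity, precipitation, wind speed, visibility, sea-level
pressure, dew point, feels-like temperature) and a daily count outcome such
as pediatric asthma visits.

## The method

For exposure *X* and daily count *Y*, lag *k* pairs *Y*<sub>t</sub> with
*X*<sub>t−k</sub>. The pipeline is the four-step causal workflow:

1. **Screen** — Spearman rank correlations between each variable and the
   counts at lags 0–6, each cell on its own lag-aligned sample; variables
   significant at the configured rule (every lag, or any lag) become
   candidate treatments.
2. **Model & identify** — a causal DAG with roles
   (treatment / outcome / confounder / unobserved). The effect is
   identified by the **backdoor criterion**: an adjustment set *Z* of
   observed non-descendants of the treatments that d-separates each
   treatment from the outcome once the treatment's outgoing edges are cut.
   The canonical choice is the observed parents of the treatments; if no
   such set blocks the backdoor paths (e.g. an unobserved confounder *U*
   causes both treatment and outcome), the package reports
   *not identified* instead of estimating.
3. **Estimate** — Poisson regression of
   *Y*<sub>t</sub> on treatments and *Z* (identity link by default, so a
   coefficient β is the **per-unit effect**: added expected visits/day per
   unit of exposure; log link with count-scale average marginal effects as
   the alternative). The **causal effect** is β × IQR(*X*) — visits/day per
   interquartile-range increase — making differently-scaled pollutants
   comparable. A joint multi-treatment model gives the **pooled** effect of
   raising all treatments by one unit (the exact coefficient sum under the
   identity link).
4. **Refute** — three robustness probes: add a random common cause (the
   estimate must not move), replace the treatment with a placebo draw (the
   estimate must vanish), re-estimate on random 80% subsets (the estimate
   must be stable). An estimate is *robust* iff all three pass.

Attribution then converts a multi-year concentration decline ΔC into annual
visits: **(ΔC / IQR) × causal effect × 365**.

Because real hospital and monitoring data of this kind are not openly
deposited, the package ships a synthetic-data generator
(`synth_config()`, `generate_environment()`, `generate_visits()`,
`generate_cohort()`) that reproduces the assumed statistical structure —
seasonal AR(1) meteorology, negatively coupled and interconverting
pollutants with multi-year declines, Poisson counts driven by lagged
exposures — with *known ground-truth effects*, so estimator recovery and
refuter calibration are testable end to end.

## Worked example

```r
library(lagcausal)

cfg <- synth_config()                      # 8-year study conditions,
env <- generate_environment(cfg, seed = 1) # true SO2 lag-5 effect 1.63
vis <- generate_visits(env, cfg$true_effects, cfg$baseline_rate,
                       cfg$link, seed = 1)

fit <- lagcausal(env, vis, build_single_treatment_dag("SO2"), lags = 0:6)
fit
#> Lagged causal Poisson model (single_with_indirect, identity link)
#>   treatments: SO2
#>   adjustment: AQI, CO, humidity, NO2, PM10, PM2.5, precipitation,
#>               sea_level_pressure, temperature, visibility, wind_speed
#>   lags: 0, 1, 2, 3, 4, 5, 6; alpha = 0.05
#>
#> Per-IQR causal effects (columns = lag):
#>      lag0  lag1  lag2 lag3   lag4   lag5   lag6
#> SO2 8.026 8.606 8.757 9.41 10.423 12.952 10.812
```

The per-IQR profile peaks at lag 5 — the lag at which the generator's true
effect was planted (truth: 1.63 visits per µg/m³ ≈ 11.7 per IQR; the lag-5
estimate 12.95 is within sampling error, and neighbouring lags pick up the
pollutant's autocorrelation). Refutation of the lag-5 estimate:

```r
refute_estimate(fit$fits$lag5, reps = 20, seed = 1)
#> Refutation (random_common_cause): 20 repetitions
#>   original effect: 1.719
#>   mean refuted:    1.719
#>   verdict:         PASS
#> Refutation (placebo_treatment): 20 repetitions
#>   original effect: 1.719
#>   mean refuted:    0.017
#>   verdict:         PASS
#> Refutation (data_subset): 20 repetitions
#>   original effect: 1.719
#>   mean refuted:    1.72
#>   verdict:         PASS
#> Estimate is ROBUST (all three probes must pass)
```

Attribution of an eight-year SO2 decline from 20.08 to 5.83 µg/m³ (IQR 7,
per-IQR causal effect 11.41):

```r
att <- attributable_visits(conc_start = 20.08, conc_end = 5.83,
                           iqr = 7, causal_effect_iqr = 11.41)
att
#> [1] 8478.038                       # avoided visits per year
reduction_share(att, 16845)
#> [1] 50.3                           # % of the observed annual reduction
```

The full orchestration — screening, selection, DAG building,
identification, estimation across model kinds, refutation, attribution,
CSV tables and a JSON run manifest — is `run_pipeline(pipeline_config(...))`
or `run_pipeline("config.yaml")`.

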