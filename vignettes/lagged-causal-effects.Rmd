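---
title: "Lagged causal effects of environmental exposures on daily visit counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged causal effects of environmental exposures on daily visit counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagcausal)
```

# The problem

Air-pollution epidemiology routinely finds daily pollutant concentrations
*correlated* with daily clinical visit counts a few days later. Correlation
is not a basis for intervention: pollutants are driven by the same weather
that may affect care-seeking, they interconvert chemically, and shared
trends induce spurious association. This package implements the
graph-based alternative: declare the causal structure explicitly, identify
which covariates license a causal reading of a regression coefficient, fit
the count model, and then attack the resulting estimate with refutation
probes before believing it.

The outcome is a daily count $Y_t$ (e.g. pediatric asthma visits); the
exposures $X_{j,t}$ are eight meteorological and seven air-pollution
variables. A lag of $k$ days pairs $Y_t$ with $X_{j,t-k}$: the exposure
strictly precedes the outcome, the standard epidemiologic convention
(`lag_align()` implements it by calendar-date arithmetic, so gaps in either
series can never cause non-adjacent days to be silently paired).

# The model

## Screening

`lag_screen()` computes, per variable and per lag $k \in \{0,\dots,6\}$,
the Spearman coefficient $r_s$ = Pearson correlation of average-ranked
data, with a two-sided p-value from
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ degrees of freedom. The
t-approximation is essentially exact at the multi-year sample sizes this
design targets ($n \approx 2900$); an exact permutation p-value
(`method = "exact"`) exists for $n \le 8$ and is used by the test suite as
an oracle. A rank statistic is used because daily counts are markedly
non-normal; no multiple-testing correction is applied across the
variable-by-lag grid — each cell is judged at $\alpha = 0.05$ on its own,
and selection (`select_treatments()`) then keeps variables significant at
*every* lag (default) or at *any* lag. The two rules differ in stringency;
both are exposed because the appropriate one depends on whether screening
is meant as a hard filter or a shortlist.

## Identification

`causal_dag()` encodes a DAG whose nodes carry roles. Two builders ship:

* `build_multiple_treatment_dag()` — 8 treatments (visibility,
  precipitation, AQI, PM2.5, PM10, SO2, NO2, CO), one outcome, four
  observed meteorological confounders (humidity, temperature, sea-level
  pressure, wind speed) and an unobserved confounder $U$; 14 nodes.
* `build_single_treatment_dag(t)` — one treatment, the outcome, and 12
  confounders (the 7 remaining treatments, the 4 meteorological variables,
  $U$). With `include_indirect = FALSE` the four meteorological variables
  — *indirect causes*, which act on the treatments but not directly on the
  outcome — are dropped, leaving 8 confounders.

Within the meteorology/pollutant block the builders fix a documented edge
list: the four meteorological confounders point at every treatment and at
the outcome; precipitation settles the six pollutant treatments; the
primary pollutants convert into the particulates and the composite index
(SO2/NO2/CO → PM2.5 → PM10 → AQI); all treatments point at the outcome
(these are the edges under test); $U$ points at the outcome. This is the
minimal acyclic structure carrying the qualitative relationships the
domain asserts (settling by precipitation and humidity, diffusion by wind,
thermal forcing, pollutant interconversion); users can assemble any other
structure from `causal_dag()` or load one from the edge-list text format.

`d_separated()` decides conditional independence by the
moralized-ancestral-graph construction, provably equivalent to the
path-wise chain/fork/collider rules; the test suite checks it against an
exhaustive path-enumeration oracle on *every* DAG structure of up to five
nodes and every conditioning set. `backdoor_set()` takes the canonical
candidate — observed, non-treatment parents of the treatments that are not
treatment descendants — and verifies it blocks every backdoor path
(d-separation in the graph with the treatments' outgoing edges removed).
The canonical choice is deterministic and always valid when any
parent-based set is; a minimal-set search is deliberately out of scope.
If verification fails, `NULL` ("not identified") is returned and every
downstream consumer refuses to produce numbers.

$U$'s edges are a modelling decision, not an estimate: by default $U$
points only at the outcome, under which the effect is identified. Setting
`u_to_treatments = TRUE` makes $U$ a parent of the treatments as well, and
the package then (correctly) declares the effect unidentified rather than
silently adjusting — this choice is deliberately explicit because drawn
graphs in applied work often leave it ambiguous.

## Estimation

`fit_outcome_model()` fits $Y_t \sim \text{Poisson}(\lambda_t)$ by IRLS
(`stats::glm`) to a relative tolerance of $10^{-8}$ within 100 iterations;
non-convergence and collinearity are errors, never silent results. Two
links are exposed:

* **identity** (default): $\lambda_t = \beta_0 + \sum_j \beta_j x_{j,t}$.
  A coefficient is directly the *per-unit effect* — added expected
  visits/day per unit of exposure — and the pooled effect of raising all
  treatments by one unit is exactly $\sum_j \beta_j$. The identity link is
  the default because per-unit effect tables in this literature read as
  additive counts (their pooled row equals the coefficient sum within
  print rounding), and because it makes the effect definition exact rather
  than an average. IRLS is started from the flat model at the mean count,
  which is always feasible for positive counts.
* **log**: $\log \lambda_t = \eta_t$. Effects are reported on the count
  scale as finite-difference *average marginal effects*,
  $\frac{1}{n}\sum_t [\hat\lambda(x_t + e_j) - \hat\lambda(x_t)]$
  (`marginal_effect()`), with the pooled version shifting all treatments
  simultaneously — in general not the coefficient sum.

Significance is a two-sided Wald test on the coefficient at
$\alpha = 0.05$. The *causal effect* reported per lag is the per-unit
effect times the variable's IQR (Q3 − Q1, linear-interpolation quantiles,
`stats::quantile` type 7). The IQR is computed once per variable on the
full unlagged series and reused at every lag, so each variable keeps a
single scaling base across its lag profile. Adjustment covariates enter at
the same lag as the treatment: confounders cause the treatment, so they
are measured contemporaneously with it (day $t-k$), not with the outcome.

`lagcausal()` wraps the sweep over lags into a classed model object with
`print`, `summary`, `coef`, `plot`, `predict`, `residuals` and `simulate`
methods; `effect_table()` reshapes to the conventional treatment-by-lag
table.

## Refutation

Three probes (`refute_estimate()`), each re-estimating under a
perturbation, with defaults of 20 repetitions, subset fraction 0.8, and
relative tolerance 0.1 — conventional values for this family of
diagnostics, exposed in every report because the literature states no
numeric thresholds:

* *random common cause*: append an independent $N(0,1)$ covariate to the
  adjustment set; pass iff the mean relative deviation of the refuted
  effects stays below the tolerance (absolute fallback when the original
  effect is numerically zero);
* *placebo treatment*: replace the treatment with an independent normal
  draw matched to its mean and SD; pass iff the mean refuted effect is
  within two standard errors of zero;
* *data subset*: re-estimate on random 80% subsets; same relative rule as
  the first probe. `fraction = 1` reproduces the original exactly, which
  the tests assert.

An estimate is *robust* iff all three pass. The refuters are pure
functions of the estimate state and a seed, and each probe draws from its
own deterministic substream.

## Attribution

`attributable_visits()` converts a period decline $\Delta C$ into annual
visits: $(\Delta C / \mathrm{IQR}) \times \text{causal effect} \times 365$
(365, not 365.25 — the published worked arithmetic this reproduces uses
calendar years). The causal effect fed in is, by default policy
(`max_significant_effect()`), the maximum significant per-IQR effect
across the lag profile. Unit tags are checked when supplied: a mg/m³
concentration decline is refused against a µg/m³ IQR rather than silently
scaled — a real hazard, since CO is conventionally reported in mg/m³
while the other pollutants use µg/m³.

# The synthetic data-generating process

Real hospital visit records and station-level monitoring data of this kind
are not openly deposited, so validation rests on a generator with known
ground truth (`synth_config()` and friends):

* **Meteorology**: annual sinusoid (mean, amplitude, day-of-year of
  seasonal peak) plus AR(1) noise.
* **Pollutants**: intercept + linear couplings to driver *anomalies*
  (negative to wind, precipitation, humidity, temperature; positive along
  the SO2/NO2/CO → PM2.5 → PM10 → AQI chain) + a linear multi-year trend +
  AR(1) noise, truncated at zero.
* **Counts**: $Y_t \sim \text{Poisson}(\lambda_t)$ with
  $\lambda_t = \max(\beta_0 + \sum \beta_{j,k} X_{j,t-k}, \varepsilon)$
  under the identity link (or $\exp$ under log). Lags reaching before the
  series start are omitted, so early days are driven by the available lags
  only.

Defaults encode the eight-year study conditions: `n_days = 2922`
(2014–2021 including two leap years), an SO2 decline from 20.08 to
5.83 µg/m³ whose spread yields an empirical IQR near 7 µg/m³, comparable
published declines for NO2 (−12.25 µg/m³) and CO (0.89 → 0.65 mg/m³), a
true effect of 1.63 visits per µg/m³ of SO2 five days earlier, and a
baseline of 54 visits/day, putting the mean daily count near 75
(≈ 217,950 visits over 2,922 days). A single integer seed feeds
independent substreams for environment, visits and cohort, so generation
is a pure function of (config, seed) and never perturbs the caller's RNG.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: zero-inflated rain (precipitation is a
smooth seasonal proxy that can go slightly negative), heteroscedastic or
regime-switching weather, nonlinear or saturating exposure–response,
overdispersed counts (the outcome is exactly Poisson), holiday/weekday
care-seeking patterns, spatial variation across monitoring stations, and
behavioural confounders such as pollen or medication stocking. Parameter
recovery on this DGP shows the estimator is correct *under its own
assumptions*; it cannot certify those assumptions for any real dataset.

The cohort generator draws sex as Bernoulli (default male share 0.6468)
and ages from a piecewise-linear quantile function through the requested
quartiles (default 3/5/7 years) bounded to [0, 18), and emits exactly one
record per counted visit.

# Numerical and procedural choices

* Follow-up deduplication (`deduplicate_visits()`): per patient, same-day
  repeats collapse, visits within the window after a retained index visit
  are dropped, and the first visit beyond the window opens a new index.
  The window defaults to 7 days ("a week" being the primary phrasing of
  the exclusion it mirrors) and is configurable — 30 reproduces a
  month-based exclusion; the operation is idempotent.
* Quantiles everywhere (IQR, age quartiles) use linear interpolation
  (type 7), the common scientific-computing default.
* Identity-link rates are floored at $10^{-8}$ in the generator;
  degenerate inputs (constant treatments, underdetermined fits, subsets
  too small to fit) are errors, not fallbacks.
* Ties in ranks take average ranks; `spearman_cor` refuses constant
  vectors, where the coefficient is undefined.
* Pipeline runs (`run_pipeline()`) log every stage with parameters, seed
  and duration, and checksum every output file into a JSON manifest; two
  runs from one config are byte-identical.

# Problem sizes in the test suite

The suite validates at the design's own scale where the claim demands it:
parameter recovery and refuter calibration use $n = 2922$ days over 50
seeds; screening type-I calibration uses 1000 independent pairs of length
200; d-separation is checked exhaustively on all ≤5-node DAG structures
(1,098 graphs, every pair, every conditioning set). Unit tests otherwise
use 120–2,000-day series, which the generator produces in milliseconds.

# Known limitations

* The canonical backdoor set is parent-based; graphs identifiable only
  through non-parent adjustment sets are reported as not identified.
* Poisson-only outcome modelling: no overdispersion or negative-binomial
  option, matching the method being validated.
* Attribution propagates no uncertainty — it is point arithmetic on point
  estimates, as in the worked examples it reproduces.
* With strongly autocorrelated exposures, single-lag models smear a true
  effect across neighbouring lags (visible in the lag profiles); the lag
  at the profile maximum is the meaningful summary, not any single
  off-peak coefficient.
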