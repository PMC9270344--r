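---
title: "Estimating LAI sensitivity to soil moisture and its trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating LAI sensitivity to soil moisture and its trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Vegetation greenness, measured as leaf area index (LAI, m²/m²), responds to
water availability in the soil. The quantity this package estimates is the
*sensitivity* ∂LAI/∂SM: the slope of the LAI **anomaly** response to
soil-moisture **anomalies**, per grid cell, separately for a near-surface
(~0–10 cm) and a sub-surface (~10–100 cm) layer. A linear regression of LAI on
one soil-moisture layer would be confounded by the other hydro-climate drivers
(temperature, precipitation, vapor pressure deficit, radiation) which covary
with soil moisture. The package therefore uses an explainable-machine-learning
decomposition:

1. fit a random forest of the LAI anomaly on six hydro-climate anomaly
   predictors (near- and sub-surface soil moisture in mm, temperature,
   precipitation, VPD, radiation);
2. isolate the marginal contribution of the chosen soil-moisture feature with
   exact TreeSHAP attributions, giving one (soil-moisture anomaly, SHAP value)
   pair per training row — the *SHAP dependence*;
3. summarize the dependence as a Theil–Sen slope (the sensitivity, LAI anomaly
   per mm) with a two-sided Kendall-τ p-value.

This assumes the cell-level interaction between LAI and soil moisture is
nearly linear; the SHAP dependence makes that assumption checkable rather than
imposed, since any nonlinearity is visible in the dependence cloud before the
robust line is fitted.

Temporal change in the coupling is estimated by recomputing the same statistic
on consecutive 3-year blocks (12 blocks for 1982–2017; a 5-year variant gives
7 blocks) and applying the Mann–Kendall test to each cell's valid block
sensitivities against the block center years.

## Preprocessing

All inputs are monthly `(time, lat, lon)` fields. The chain per grid cell:

* **Soil-layer aggregation.** Volumetric layers (m³/m³) convert to water depth
  via layer thickness: `mm = θ × thickness_mm`. Layers with bottoms at or
  above the split depth (default 0.07 m) sum to the near-surface store, the
  rest to the sub-surface store, mirroring the ERA5-Land layering (0–7, 7–28,
  28–100 cm). Total water is conserved by construction.
* **Growing-season mask.** A step is valid iff air temperature > 5 °C and the
  raw-signal ensemble-mean LAI > 0.5 (both strict inequalities); negative
  vegetation-index values are filtered when index fields are supplied.
* **De-seasonalizing.** Subtract the long-term mean of each calendar month,
  computed over valid steps only; months observed fewer than twice at a cell
  are flagged missing rather than estimated.
* **De-trending.** Subtract a LOWESS smoother (tricube weights, locally
  linear) with span 0.4, run on the *valid-step index* rather than calendar
  time — gaps from masked winters would otherwise dominate the local windows.
  The smoother uses a single pass (no robustness iterations); with anomalies
  already centred, robustness reweighting changes residuals negligibly while
  costing determinism of interpretation across implementations. Cells with
  fewer than 10 valid points are flagged missing.

De-seasonalizing precedes de-trending, following the order in which the two
corrections are conventionally stated for this analysis; a diagnostic test
confirms the two orders correlate > 0.95 on AR(1)-type data, so the choice is
not load-bearing.

## The per-cell model and its gates

Training tables pool the 3×3 neighborhood of each core cell (boundary cells
use existing neighbors), one row per valid time step per cell. Two removal
rules apply, both strict:

* tables with ≤ 50 rows (overall) or ≤ 15 rows (per block) are flagged
  *insufficient data* and never fitted;
* fitted forests whose out-of-bag R² (1 − SSE_oob/SST, i.e. skill against
  predicting the training mean) is ≤ 0 are flagged *gated out*.

Forest hyperparameters: 100 trees; 30 % of features tried per split, read as
`mtry = max(1, round(0.3 × 6)) = 2` — the nearest-integer reading; truncating
1.8 down to a single random feature per split makes five of six split
candidates uninformative and measurably biases the recovered slope toward
zero; base random state 42, with per-cell seeds derived deterministically so
maps are reproducible bit-for-bit and independent of evaluation order.
The minimum leaf size (`nodesize = 25`) is not specified by the method being
implemented; 25 was fixed once as the package default for the pooled anomaly
tables (hundreds to thousands of rows), trading a small amount of dependence
resolution for substantially smaller trees. The parameter-recovery tests run
at this default.

TreeSHAP is computed with the exact path-dependent polynomial algorithm over
the forest's own trees, marginalizing absent features by the cover-weighted
flow of each tree's in-bag bootstrap sample. Attributions satisfy the
efficiency axiom (`rowSums(phi) + base` equals the forest prediction to
machine precision); the test suite verifies the implementation against a
brute-force Shapley enumeration (2^p subsets with cover-weighted conditional
expectations). SHAP dependence pairs are taken from all pooled training rows
(`dependence_rows = "pooled"`); a `"core"` variant restricts to core-cell
rows.

Per-block models re-gate on their own out-of-bag skill, and block estimates
with Theil–Sen p ≥ 0.1 are flagged invalid, so trend detection only sees
blocks where the dependence was resolvable.

## Trend analysis and attribution

* **Soil-moisture-controlled mask:** cells with significantly positive
  overall sensitivity (slope > 0, p < 0.1). Only these cells enter trend
  analysis; negative or non-significant cells are treated as
  energy-controlled and excluded.
* **Per-cell trends:** Mann–Kendall on valid block sensitivities against
  block center years (at least 4 valid blocks), with the standard
  tie-corrected variance and continuity correction; the Sen slope is the
  all-pairs median slope. Two-sided per-cell significance is reported at
  p < 0.1. No multiple-testing correction is applied across cells — per-cell
  tests are reported descriptively and field significance is deliberately not
  assessed.
* **Global series:** the area-weighted (cos-latitude) median of valid block
  sensitivities over controlled cells, re-based to the first block, tested
  with Mann–Kendall at p < 0.01. The median (rather than mean) is the default
  aggregate for robustness to the skewed per-cell distribution.
* **Area fractions:** cos-latitude-weighted fractions of the study area
  (total vegetation cover ≥ 5 %, irrigation ≤ 10 %, inclusive bounds) with
  increasing/decreasing trends, plus the p < 0.1 subsets; excluded cells stay
  in the denominator so the partition sums to one.
* **Response functions:** significantly sensitive cells (p < 0.01) binned by
  growing-season mean soil moisture; per-bin median and interquartile range.
* **Regime comparison:** cells binned over (aridity index, long-term mean
  temperature); per regime the mean difference and Pearson correlation of two
  sensitivity maps. The aridity index is mean net radiation over
  latent-heat-converted precipitation (λ = 2.45 MJ/kg, the standard FAO
  value); AI > 1 is dry. Default regime edges: aridity {0.5, 1, 2},
  temperature quartiles — both configurable, since the canonical analysis
  does not state them.
* **Attribution:** one random forest (same hyperparameters) of the per-cell
  trend on per-cell predictors — overall sensitivity, Sen-slope trends of
  growing-season annual means of precipitation, both soil-moisture stores,
  temperature, radiation and VPD, and the non-tree cover fraction — ranked by
  mean |SHAP|. The two top-ranked controls define a two-way table of median
  trends with cell counts.

## The synthetic-data generator

Real multi-decade satellite and reanalysis products are outside the scope of
a desk-scale package, so the generator provides gridded inputs with the
statistical structure the analysis assumes *and known ground truth*:

* each variable = monthly climatology (cosine, July peak) + linear long-term
  drift + stationary AR(1) Gaussian anomaly (lag-1 autocorrelation 0.5 by
  default);
* the LAI anomaly adds `b(t)·SMsub_anom + b_near·SMnear_anom +
  temp_effect·T_anom + ε`, with `b(t) = b₀ + drift·(t − t₀)` — a linear ramp
  is the minimal signal for a monotone-trend test;
* soil moisture is emitted as three volumetric layers (0–7, 7–28, 28–100 cm)
  so the depth-weighted mm conversion is exercised;
* default study conditions: an 8×8-cell 0.5° grid at 48–52° N, monthly
  1982–2017, b₀ = 0.5 LAI anomaly per mm (sub-surface), 0.2 (near-surface),
  temperature effect 0.05 per °C, LAI noise sd 0.2, soil-moisture anomaly sd
  1 mm (sub) and 0.6 mm (near). The boreal-temperate temperature climatology
  (mean 2 °C, amplitude 14 °C, weak latitudinal gradient) yields a ~5-month
  growing season, so the growing-season filter removes a substantial share of
  steps without emptying any cell. A longitudinal precipitation gradient
  creates aridity contrast for the regime machinery.

These sizes keep a full end-to-end study (preprocessing, 64 gated forests
with exact SHAP, 12 block refits per cell, trends, attribution) at a few
minutes on one CPU.

What the generator does *not* emulate: sensor artifacts (orbital drift,
instrument degradation), realistic spatial covariance of climate fields,
non-Gaussian anomaly distributions, and land-cover change over time.
Passing parameter-recovery tests therefore demonstrates that the estimation
chain is unbiased enough and its tests hold their nominal size *under the
assumed anomaly model* — not that any particular satellite product satisfies
that model. The marginal distribution of real anomalies is unknown; Gaussian
AR(1) is an assumption of convenience, defensible because the downstream
statistics (Theil–Sen, Mann–Kendall, Kendall-τ) are rank-based and
distribution-free.

## Numerical choices and degenerate inputs

* Theil–Sen pairs with identical x are dropped; an all-identical x errors.
  A constant y gives slope 0 with p = 1.
* Kendall p-values use the normal approximation with tie correction
  (`exact = FALSE`) at every n, so p-values are comparable across block sizes.
* Mann–Kendall: `Z = (S ∓ 1)/√var(S)` continuity correction; an all-ties
  series returns S = 0, p = 1 rather than dividing by zero.
* The weighted median is the type-1 weighted quantile (smallest value whose
  cumulative weight reaches one half).
* Zero mean precipitation with positive radiation maps to an infinite
  (maximally arid) aridity index, not a division error.
* Missing data propagate as flags (`NA` / status codes), never as zeros;
  `insufficient` (never fitted) is kept distinct from `gated` (fitted, no
  out-of-bag skill).

## Reproducibility

Every map is a pure function of (inputs, configuration): generator output is
determined by its seed, per-cell forests by seeds derived from the
configuration's random state and the cell (and block) index, and pipeline
artifacts embed a hash of the serialized configuration plus the seed.
Re-running a pipeline with the same configuration is bit-identical.

## Known limitations

* The sensitivity is a robust linear summary of a possibly nonlinear
  dependence; strongly nonlinear cells are summarized, not resolved.
* The OOB gate selects on model skill, which can correlate with the quantity
  of interest; cells with weak but real coupling may be discarded.
* Tree ensembles flatten the extremes of the dependence, biasing recovered
  slopes a few percent toward zero even in the linear noise-free case; the
  recovery tests bound this at the package defaults.
* Per-cell significance is descriptive: no field-significance or
  spatial-autocorrelation correction is attempted.
* The attribution model is associative across cells; it ranks controls, it
  does not establish causation.
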