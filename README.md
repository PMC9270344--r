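# vegsens

Estimating the sensitivity of vegetation greenness (leaf area index, LAI) to
near-surface and sub-surface soil moisture from gridded monthly fields, with
explainable machine learning — and detecting long-term trends in that
sensitivity and their hydro-climate controls.

## Who this is for

Land–vegetation interaction researchers who want the full estimation chain —
growing-season anomaly preprocessing, per-cell gated random forests, exact
TreeSHAP dependence, robust slope and trend statistics, attribution — as
tested, reusable R functions rather than a one-off analysis script. The
pipeline is input-agnostic: any co-registered monthly LAI + hydro-climate
fields in CF-style NetCDF work, and a synthetic generator with known ground
truth supports method validation end to end.

## The statistic at the core

Per grid cell, the sensitivity ∂LAI/∂SM is estimated as:

1. **Anomalies.** Each monthly field is restricted to the growing season
   (temperature > 5 °C, raw ensemble-mean LAI > 0.5), de-seasonalized
   (subtract long-term mean monthly signals) and de-trended (subtract a
   LOWESS smoother, span 0.4). Volumetric soil layers are converted to water
   depth (mm = θ × layer thickness) and aggregated to near-surface (0–7 cm)
   and sub-surface (7–100 cm) stores.
2. **Model.** A random forest (100 trees, 30 % max features, random state 42)
   of LAI anomalies on six hydro-climate anomaly predictors, trained on the
   3×3 pooled neighborhood if more than 50 points exist, and kept only if its
   out-of-bag R² exceeds 0.
3. **SHAP dependence.** Exact TreeSHAP attributions isolate the marginal
   contribution of the chosen soil-moisture layer; the Theil–Sen slope of
   (SM anomaly, SHAP value) pairs is the sensitivity (LAI anomaly per mm),
   with a two-sided Kendall-τ p-value (significance at p < 0.01).
4. **Trends.** The same statistic on 3-year blocks (more than 15 points per
   block, re-gated, blocks with p ≥ 0.1 dropped), then Mann–Kendall with Sen
   slope per soil-moisture-controlled cell (positive overall sensitivity,
   p < 0.1), area-weighted global aggregation, and cos-latitude area
   fractions of increasing/decreasing regions.
5. **Attribution.** A forest of the per-cell trend on hydro-climate and
   ecological predictors across cells, ranked by mean |SHAP|, plus the
   two-way grouping of trends by the top two controls.

See `vignettes/soil-moisture-sensitivity.Rmd` for the full method account,
parameter defaults and design rationale.

## Worked example

A small synthetic study (4×4 cells, monthly 2000–2011, imposed sub-surface
sensitivity 0.5 LAI anomaly per mm, no drift):

```r
library(vegsens)
cfg <- pipeline_config(synth = synth_config(n_lat = 4, n_lon = 4,
                                            start_year = 2000, end_year = 2011))
res <- run_pipeline(cfg, quiet = TRUE)
print(res$sensitivity)
#> <sensitivity_map> dLAI/dSMsub on 4 x 4 grid
#>   ok 16 | gated 0 | insufficient 0 | missing 0
#>   slope median 0.4016 [IQR 0.3816, 0.4083] LAI anomaly per mm
summary(res$sensitivity)
#> Overall LAI sensitivity to sub-surface soil moisture
#>   cells estimated: 16 of 16
#>   significant (p < 0.01): 16 (16 positive)
#>   median slope: 0.4016 LAI anomaly per mm | median OOB R2: 0.738
print(res$trends)
#> <trend_map> Sen slope of 3-year-block sensitivity
#>   cells: ok 16 | insufficient 0 | excluded 0
#>   increasing 6 | decreasing 10 | significant (p < 0.1) 0
print(res$global_series)
#> <global_series> area-weighted median over 4 blocks
#>   MK Sen slope -0.002199 per year, p = 0.308
```

Reading the output: every cell's forest beat the out-of-bag gate (median OOB
R² 0.74) and all 16 Theil–Sen slopes are significantly positive; the median
recovered slope (0.40) sits somewhat below the imposed 0.5 because tree
ensembles flatten the extremes of the dependence — the attenuation shrinks
with record length (the 36-year default grid recovers ≈ 0.46). With no
imposed drift, block sensitivities scatter without a Mann–Kendall-significant
trend anywhere (0 of 16 cells at p < 0.1; global p = 0.31), as they should.

With `run_pipeline(cfg, out_dir = "artifacts")` the run also writes NetCDF
maps (`sensitivity.nc`, `trends.nc`), CSV tables (area fractions, response
function, attribution ranking), `summary.json`, the resolved `config.yaml`
and a log, all stamped with the configuration hash and seed; reruns are
bit-identical. A thin CLI wrapper lives in `inst/scripts/vegsens.R`
(`generate` and `run` subcommands).

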