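Package: vegsens
Title: Sensitivity of Vegetation Greenness to Soil Moisture via Explainable Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the sensitivity of leaf area index (LAI) to near-surface and
    sub-surface soil moisture from gridded monthly fields. Raw fields are turned into
    growing-season anomalies (soil-layer aggregation with unit conversion, temperature
    and greenness masking, de-seasonalizing, LOWESS de-trending); per grid cell a
    random-forest model of LAI anomalies on six hydro-climate predictors is fitted on
    3x3 pooled neighborhoods, gated on out-of-bag skill, and summarized as the
    Theil-Sen slope of the exact TreeSHAP dependence on the chosen soil-moisture
    layer. Block-wise re-estimation with Mann-Kendall testing detects long-term trends
    in that sensitivity, and a SHAP-based attribution stage ranks hydro-climate and
    ecological controls of the trend pattern. A synthetic-data generator with known
    ground truth supports parameter-recovery testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    ncdf4,
    randomForest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
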