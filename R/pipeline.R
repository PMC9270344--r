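#' Pipeline configuration
#'
#' One object holding every numeric constant of the analysis: preprocessing
#' thresholds (temperature 5 degC, raw LAI 0.5, LOWESS span 0.4, soil split
#' depth 0.07 m), study-area rules (cover >= 0.05, irrigation <= 0.10),
#' significance levels (overall p < 0.01; controlled-region, per-block and
#' per-cell-trend p < 0.1; global trend p < 0.01), the block length, the
#' random-forest configuration, and the synthetic-data configuration used
#' when no input directory is given. Serializes losslessly to/from YAML.
#'
#' @param input optional fixture directory (see [write_fixture()]); when
#'   `NULL` the synthetic generator provides the inputs.
#' @param synth a [synth_config()] (used when `input` is `NULL`).
#' @param layer `"sub"` or `"near"`.
#' @param block_years 3 (default) or 5.
#' @param temp_threshold,lai_threshold,span,split_depth preprocessing
#'   parameters.
#' @param cover_min,irrigation_max study-area thresholds.
#' @param alpha_overall,alpha_controlled,alpha_block,alpha_trend,alpha_global
#'   significance levels.
#' @param rf an [rf_config()].
#' @param seed integer seed for the generator (overrides `synth$seed` when
#'   supplied).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synth = synth_config(),
                            layer = c("sub", "near"), block_years = 3L,
                            temp_threshold = 5, lai_threshold = 0.5,
                            span = 0.4, split_depth = 0.07,
                            cover_min = 0.05, irrigation_max = 0.10,
                            alpha_overall = 0.01, alpha_controlled = 0.1,
                            alpha_block = 0.1, alpha_trend = 0.1,
                            alpha_global = 0.01,
                            rf = rf_config(), seed = NULL) {
  stopifnot(block_years >= 1L, span > 0, span <= 1,
            cover_min >= 0, cover_min <= 1, irrigation_max >= 0,
            irrigation_max <= 1)
  for (a in c(alpha_overall, alpha_controlled, alpha_block, alpha_trend,
              alpha_global))
    stopifnot(a > 0, a < 1)
  if (!is.null(seed)) synth$seed <- as.integer(seed)
  structure(list(input = input, synth = synth, layer = match.arg(layer),
                 block_years = as.integer(block_years),
                 temp_threshold = temp_threshold, lai_threshold = lai_threshold,
                 span = span, split_depth = split_depth,
                 cover_min = cover_min, irrigation_max = irrigation_max,
                 alpha_overall = alpha_overall,
                 alpha_controlled = alpha_controlled,
                 alpha_block = alpha_block, alpha_trend = alpha_trend,
                 alpha_global = alpha_global, rf = rf),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `config_to_yaml` returns `path` invisibly; `config_from_yaml`
#'   returns a `pipeline_config`.
#' @export
config_to_yaml <- function(config, path) {
  x <- unclass(config)
  x$rf <- unclass(x$rf)
  x$synth <- unclass(x$synth)
  x$synth[c("anomaly_sd", "climatology_means", "seasonal_amplitudes",
            "longterm_trends")] <-
    lapply(x$synth[c("anomaly_sd", "climatology_means", "seasonal_amplitudes",
                     "longterm_trends")], as.list)
  for (nm in c("base_sensitivity_sub", "sensitivity_trend_sub",
               "base_sensitivity_near", "tree_cover", "nontree_cover",
               "irrigation_fraction")) {
    v <- x$synth[[nm]]
    if (is.matrix(v))
      x$synth[[nm]] <- lapply(seq_len(nrow(v)), function(r) unname(v[r, ]))
  }
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  sy <- x$synth
  for (nm in c("anomaly_sd", "climatology_means", "seasonal_amplitudes",
               "longterm_trends"))
    sy[[nm]] <- unlist(sy[[nm]])
  for (nm in c("base_sensitivity_sub", "sensitivity_trend_sub",
               "base_sensitivity_near", "tree_cover", "nontree_cover",
               "irrigation_fraction"))
    if (is.list(sy[[nm]]) || length(sy[[nm]]) > 1L)
      sy[[nm]] <- do.call(rbind, lapply(sy[[nm]], unlist))
  synth <- do.call(synth_config, sy)
  pipeline_config(input = x$input, synth = synth, layer = x$layer,
                  block_years = x$block_years,
                  temp_threshold = x$temp_threshold,
                  lai_threshold = x$lai_threshold, span = x$span,
                  split_depth = x$split_depth, cover_min = x$cover_min,
                  irrigation_max = x$irrigation_max,
                  alpha_overall = x$alpha_overall,
                  alpha_controlled = x$alpha_controlled,
                  alpha_block = x$alpha_block, alpha_trend = x$alpha_trend,
                  alpha_global = x$alpha_global,
                  rf = do.call(rf_config, x$rf))
}

# rolling polynomial hash of the serialized configuration (provenance stamp)
config_hash <- function(config) {
  s <- yaml::as.yaml(rapply(unclass(config), unclass, how = "replace"))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full sensitivity-trend pipeline
#'
#' Executes the stages in order — input (synthetic generation or fixture
#' read), soil-layer aggregation, anomaly preprocessing, static masks,
#' overall sensitivity, block sensitivity, trend detection, global
#' aggregation, area fractions, response function, and attribution — and, if
#' `out_dir` is given, writes NetCDF maps, CSV tables, a JSON summary, the
#' resolved YAML configuration and a log, each stamped with the configuration
#' hash and seed. Reruns with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @param overwrite overwrite an existing `out_dir`.
#' @param quiet suppress per-stage messages.
#' @return list of class `vegsens_run` with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         overwrite = FALSE, quiet = FALSE) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  hash <- config_hash(config)
  say("run %s | seed %d | layer %s | blocks %dy", hash, config$synth$seed,
      config$layer, config$block_years)

  say("stage input")
  ds <- if (is.null(config$input)) generate_dataset(config$synth)
  else read_fixture(config$input)

  say("stage preprocess")
  sm <- aggregate_soil_layers(ds$fields$sm_layers,
                              attr(ds$fields$sm_layers, "depths"),
                              config$split_depth)
  anoms <- build_anomaly_dataset(ds$fields$lai, sm$smnear, sm$smsub,
                                 ds$fields$temp, ds$fields$precip,
                                 ds$fields$vpd, ds$fields$rad,
                                 temp_threshold = config$temp_threshold,
                                 lai_threshold = config$lai_threshold,
                                 span = config$span)
  say("  growing-season valid steps: %.1f%%", 100 * mean(anoms$valid_mask))

  say("stage masks")
  study <- study_area_mask(ds$static$tree_cover, ds$static$nontree_cover,
                           ds$static$irrigation_fraction,
                           config$cover_min, config$irrigation_max)
  aridity <- aridity_index(ds$fields$rad, ds$fields$precip)
  mean_temp <- apply(ds$fields$temp$values, c(2, 3), mean, na.rm = TRUE)
  regimes <- climate_regime_bins(aridity, mean_temp, study_area = study)
  say("  study area: %d of %d cells", sum(study), length(study))

  say("stage overall sensitivity")
  cells <- which(study, arr.ind = TRUE)
  sens <- overall_sensitivity(anoms, config$layer, config$rf, cells = cells)
  say("  ok %d | gated %d | insufficient %d",
      sum(sens$status == "ok"), sum(sens$status == "gated"),
      sum(sens$status == "insufficient"))
  controlled <- sm_controlled_mask(sens, config$alpha_controlled) & study
  say("  soil-moisture-controlled cells: %d", sum(controlled))

  say("stage block sensitivity")
  blocks <- block_sensitivity(anoms, config$layer, config$rf,
                              config$block_years, config$alpha_block,
                              cells = cells)
  say("  valid block estimates: %d of %d",
      sum(blocks$valid), length(blocks$valid))

  say("stage trends")
  trends <- trend_map(blocks, controlled, config$alpha_trend)
  glob <- if (any(controlled)) global_series(blocks, controlled,
                                             alpha = config$alpha_global)
  else NULL
  fracs <- area_fractions(trends, study, alpha = config$alpha_trend)
  say("  increasing %.1f%% | decreasing %.1f%%",
      100 * fracs$increasing, 100 * fracs$decreasing)

  say("stage response function")
  gs_mean_sm <- {
    f <- if (config$layer == "sub") sm$smsub else sm$smnear
    v <- f$values; v[!anoms$valid_mask] <- NA
    apply(v, c(2, 3), mean, na.rm = TRUE)
  }
  resp <- tryCatch(response_function(sens, gs_mean_sm,
                                     p_threshold = config$alpha_overall),
                   error = function(e) { say("  skipped: %s", conditionMessage(e)); NULL })

  say("stage attribution")
  nontree_frac <- ds$static$nontree_cover /
    pmax(ds$static$tree_cover + ds$static$nontree_cover, 1e-12)
  preds <- list(
    overall_sensitivity = sens$slope,
    precip_trend = predictor_trends(ds$fields$precip, anoms$valid_mask),
    smnear_trend = predictor_trends(sm$smnear, anoms$valid_mask),
    smsub_trend = predictor_trends(sm$smsub, anoms$valid_mask),
    temp_trend = predictor_trends(ds$fields$temp, anoms$valid_mask),
    rad_trend = predictor_trends(ds$fields$rad, anoms$valid_mask),
    vpd_trend = predictor_trends(ds$fields$vpd, anoms$valid_mask),
    nontree_fraction = nontree_frac)
  attrib <- tryCatch(attribute_trends(trends$sen_slope, preds, config$rf),
                     error = function(e) { say("  skipped: %s", conditionMessage(e)); NULL })
  grouping <- if (!is.null(attrib))
    tryCatch(group_by_top2(trends, preds$precip_trend,
                           preds$overall_sensitivity),
             error = function(e) NULL)
  else NULL

  res <- structure(list(config = config, hash = hash, dataset = ds,
                        anomalies = anoms, study_area = study,
                        aridity = aridity, mean_temp = mean_temp,
                        regimes = regimes, sensitivity = sens,
                        controlled = controlled, blocks = blocks,
                        trends = trends, global_series = glob,
                        area_fractions = fracs, response = resp,
                        attribution = attrib, grouping = grouping,
                        log = log),
                   class = "vegsens_run")
  if (!is.null(out_dir)) write_run(res, out_dir, overwrite)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(res)
}

matrix_field <- function(m, lat, lon, units, name) {
  grid_field(array(m, c(1, nrow(m), ncol(m))), units,
             as.Date("1970-01-01"), lat, lon, name)
}

write_run <- function(res, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && !overwrite)
    stop(sprintf("'%s' exists; use overwrite = TRUE", out_dir), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lat <- res$sensitivity$lat; lon <- res$sensitivity$lon
  stamp <- list(config_hash = res$hash, seed = res$config$synth$seed)
  mf <- function(m, units, name) matrix_field(m, lat, lon, units, name)
  write_grid(list(slope = mf(res$sensitivity$slope, "LAI anomaly per mm", "slope"),
                  p_value = mf(res$sensitivity$p_value, "1", "p_value"),
                  oob_r2 = mf(res$sensitivity$oob_r2, "1", "oob_r2"),
                  n_samples = mf(res$sensitivity$n_samples + 0, "1", "n_samples")),
             file.path(out_dir, "sensitivity.nc"), stamp)
  write_grid(list(sen_slope = mf(res$trends$sen_slope, "per year", "sen_slope"),
                  mk_p = mf(res$trends$mk_p, "1", "mk_p"),
                  n_blocks = mf(res$trends$n_blocks + 0, "1", "n_blocks")),
             file.path(out_dir, "trends.nc"), stamp)
  write.csv(data.frame(res$area_fractions),
            file.path(out_dir, "area_fractions.csv"), row.names = FALSE)
  if (!is.null(res$response))
    write.csv(res$response, file.path(out_dir, "response_function.csv"),
              row.names = FALSE)
  if (!is.null(res$attribution))
    write.csv(res$attribution$importance,
              file.path(out_dir, "attribution_importance.csv"),
              row.names = FALSE)
  summary_json <- list(
    config_hash = res$hash, seed = res$config$synth$seed,
    n_study_cells = sum(res$study_area),
    n_controlled = sum(res$controlled),
    area_fractions = res$area_fractions,
    global_trend = if (!is.null(res$global_series))
      list(sen_slope = res$global_series$mk$sen_slope,
           p_value = res$global_series$mk$p_value,
           significant = res$global_series$significant))
  writeLines(jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "summary.json"))
  config_to_yaml(res$config, file.path(out_dir, "config.yaml"))
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
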