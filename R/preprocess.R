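#' Aggregate volumetric soil-moisture layers to near- and sub-surface water depth
#'
#' Converts each volumetric layer (m3/m3) to a water depth (mm) via its layer
#' thickness and sums layers above/below a split depth, following the
#' ERA5-Land convention of layer 1 (0-7 cm) as near-surface and the depth
#' weighting of layers 2 (7-28 cm) and 3 (28-100 cm) as sub-surface.
#'
#' @param layer_fields list of `grid_field`s in m3/m3, ordered top-down.
#' @param layer_depths list of `c(top, bottom)` in metres, contiguous and
#'   non-overlapping.
#' @param split_depth depth (m) separating near from sub; must coincide with a
#'   layer boundary.
#' @return list with `smnear` and `smsub` `grid_field`s in mm.
#' @export
aggregate_soil_layers <- function(layer_fields, layer_depths, split_depth = 0.07) {
  if (length(layer_fields) != length(layer_depths))
    stop("one depth pair per layer field required", call. = FALSE)
  for (f in layer_fields)
    if (!identical(f$units, "m3/m3"))
      stop(sprintf("layer units must be m3/m3, got '%s'", f$units), call. = FALSE)
  do.call(stopifnot_same_grid, layer_fields)
  tops <- vapply(layer_depths, `[`, numeric(1), 1L)
  bots <- vapply(layer_depths, `[`, numeric(1), 2L)
  if (any(bots <= tops)) stop("layer bottoms must exceed tops", call. = FALSE)
  if (length(tops) > 1L && any(abs(tops[-1L] - bots[-length(bots)]) > 1e-9))
    stop("layers must be contiguous and non-overlapping", call. = FALSE)
  bounds <- c(tops[1L], bots)
  if (!any(abs(bounds - split_depth) < 1e-9))
    stop("split_depth must coincide with a layer boundary", call. = FALSE)

  thick_mm <- 1000 * (bots - tops)
  ref <- layer_fields[[1L]]
  acc <- function(idx) {
    out <- array(0, dim(ref$values))
    for (k in idx) out <- out + layer_fields[[k]]$values * thick_mm[k]
    out
  }
  near_idx <- which(bots <= split_depth + 1e-9)
  sub_idx  <- setdiff(seq_along(layer_fields), near_idx)
  list(smnear = grid_field(acc(near_idx), "mm", ref$time, ref$lat, ref$lon, "smnear"),
       smsub  = grid_field(acc(sub_idx),  "mm", ref$time, ref$lat, ref$lon, "smsub"))
}

#' Growing-season mask
#'
#' A time step at a cell is growing season iff air temperature exceeds 5 degC
#' (strict) and the raw-signal ensemble-mean LAI exceeds 0.5 (strict); where
#' vegetation-index fields are supplied, negative index values are filtered
#' out as well.
#'
#' @param temperature `grid_field` in degC.
#' @param lai_ensemble_mean `grid_field` of raw (not anomaly) LAI.
#' @param vegetation_index_fields optional list of `grid_field`s whose
#'   negative values invalidate a step.
#' @param temp_threshold,lai_threshold thresholds (strict inequalities).
#' @return logical `(time, lat, lon)` array.
#' @export
growing_season_mask <- function(temperature, lai_ensemble_mean,
                                vegetation_index_fields = NULL,
                                temp_threshold = 5, lai_threshold = 0.5) {
  stopifnot_same_grid(temperature, lai_ensemble_mean)
  m <- !is.na(temperature$values) & !is.na(lai_ensemble_mean$values) &
    temperature$values > temp_threshold & lai_ensemble_mean$values > lai_threshold
  for (vi in vegetation_index_fields) {
    stopifnot_same_grid(temperature, vi)
    m <- m & !is.na(vi$values) & vi$values >= 0
  }
  m
}

#' Remove the mean seasonal cycle from a monthly field
#'
#' Per cell and calendar month, subtracts the long-term mean of that month
#' computed over valid (mask-true, non-missing) steps. Months with fewer than
#' `min_obs` valid occurrences at a cell are flagged missing there; masked-out
#' steps are missing in the output.
#'
#' @param field a `grid_field`.
#' @param mask optional logical `(time, lat, lon)` validity mask.
#' @param min_obs minimum valid occurrences per calendar month (default 2).
#' @return a `grid_field` of anomalies (same units).
#' @export
deseasonalize <- function(field, mask = NULL, min_obs = 2L) {
  v <- field$values
  if (is.null(mask)) mask <- array(TRUE, dim(v))
  if (!identical(dim(mask), dim(v))) stop("mask does not match field", call. = FALSE)
  valid <- mask & !is.na(v)
  mon <- month_of(field$time)
  out <- array(NA_real_, dim(v))
  for (m in unique(mon)) {
    sel <- mon == m
    vm <- v[sel, , , drop = FALSE]
    ok <- valid[sel, , , drop = FALSE]
    vm[!ok] <- NA_real_
    nobs <- apply(ok, c(2, 3), sum)
    mu <- apply(vm, c(2, 3), function(z) mean(z, na.rm = TRUE))
    mu[nobs < min_obs] <- NA_real_
    out[sel, , ] <- sweep(vm, c(2, 3), mu, "-")
  }
  grid_field(out, field$units, field$time, field$lat, field$lon,
             paste0(field$name, "_anom"))
}

#' LOWESS de-trending of a valid-step series
#'
#' Subtracts a locally weighted (tricube, locally linear) smoothing of the
#' series against its valid-step index, with the smoothing span expressed as a
#' fraction of the valid points. Series with fewer than `min_points` valid
#' values are returned all-missing.
#'
#' @param series numeric vector (may contain `NA`).
#' @param span smoothing span in (0, 1], fraction of valid points (default 0.4).
#' @param min_points minimum valid points (default 10).
#' @return residual series, same length, `NA` where input was missing.
#' @export
detrend_lowess <- function(series, span = 0.4, min_points = 10L) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  ok <- !is.na(series)
  out <- rep(NA_real_, length(series))
  if (sum(ok) < min_points) return(out)
  idx <- which(ok)
  fit <- lowess(seq_along(idx), series[idx], f = span, iter = 0)
  out[idx] <- series[idx] - fit$y
  out
}

#' Build the growing-season anomaly dataset
#'
#' The preprocessing chain applied identically to LAI and the six hydro-climate
#' predictors: growing-season masking, de-seasonalizing, then per-cell LOWESS
#' de-trending of the valid-step sequence.
#'
#' @param lai,smnear,smsub,temp,precip,vpd,rad co-registered `grid_field`s
#'   (soil moisture already aggregated to mm).
#' @param lai_raw raw-signal ensemble-mean LAI used (with `temp`) for the
#'   growing-season mask; defaults to `lai`.
#' @param vegetation_index_fields optional index fields whose negative values
#'   are filtered out.
#' @param temp_threshold,lai_threshold,span preprocessing parameters.
#' @return an `anomaly_dataset`: anomaly `grid_field`s `lai`, `smnear`,
#'   `smsub`, `temp`, `precip`, `vpd`, `rad`, plus `valid_mask`, coordinates
#'   and calendar.
#' @export
build_anomaly_dataset <- function(lai, smnear, smsub, temp, precip, vpd, rad,
                                  lai_raw = lai, vegetation_index_fields = NULL,
                                  temp_threshold = 5, lai_threshold = 0.5,
                                  span = 0.4) {
  fields <- list(lai = lai, smnear = smnear, smsub = smsub, temp = temp,
                 precip = precip, vpd = vpd, rad = rad)
  do.call(stopifnot_same_grid, c(fields, list(lai_raw)))
  mask <- growing_season_mask(temp, lai_raw, vegetation_index_fields,
                              temp_threshold, lai_threshold)
  anoms <- lapply(fields, function(f) {
    a <- deseasonalize(f, mask)
    d <- dim(a$values)
    for (i in seq_len(d[2])) for (j in seq_len(d[3]))
      a$values[, i, j] <- detrend_lowess(a$values[, i, j], span = span)
    a
  })
  structure(c(anoms, list(valid_mask = mask,
                          time = lai$time, lat = lai$lat, lon = lai$lon)),
            class = "anomaly_dataset")
}

#' @export
print.anomaly_dataset <- function(x, ...) {
  d <- dim(x$valid_mask)
  cat(sprintf("<anomaly_dataset> %d months x %d x %d | %.1f%% growing-season valid\n",
              d[1], d[2], d[3], 100 * mean(x$valid_mask)))
  invisible(x)
}
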