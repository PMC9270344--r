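mk_field <- function(vals, units = "m3/m3", name = "f") {
  d <- dim(vals)
  time <- seq(as.Date("2000-01-01"), by = "month", length.out = d[1])
  grid_field(vals, units, time, 40 + 0.5 * seq_len(d[2]),
             10 + 0.5 * seq_len(d[3]), name)
}

test_that("soil-layer aggregation applies the depth-weighted unit conversion", {
  dims <- c(6, 2, 2)
  l2 <- mk_field(array(0.3, dims))
  l3 <- mk_field(array(0.2, dims))
  agg <- aggregate_soil_layers(list(l2, l3), list(c(0.07, 0.28), c(0.28, 1.0)),
                               split_depth = 0.07)
  # theta = 0.3 over 210 mm plus theta = 0.2 over 720 mm
  expect_equal(agg$smsub$values, array(0.3 * 210 + 0.2 * 720, dims))
  expect_equal(unique(as.vector(agg$smsub$values)), 207)
  expect_identical(agg$smsub$units, "mm")

  single <- aggregate_soil_layers(list(mk_field(array(0.5, dims))),
                                  list(c(0, 0.07)), split_depth = 0.07)
  expect_equal(single$smnear$values, array(35, dims))

  zero <- aggregate_soil_layers(list(mk_field(array(0, dims))),
                                list(c(0, 0.07)), split_depth = 0.07)
  expect_equal(unique(as.vector(zero$smnear$values)), 0)
})

test_that("layer aggregation conserves total water and validates inputs", {
  dims <- c(6, 2, 2)
  set.seed(3)
  layers <- list(mk_field(array(runif(prod(dims)), dims)),
                 mk_field(array(runif(prod(dims)), dims)),
                 mk_field(array(runif(prod(dims)), dims)))
  depths <- list(c(0, 0.07), c(0.07, 0.28), c(0.28, 1.0))
  agg <- aggregate_soil_layers(layers, depths, 0.07)
  total <- layers[[1]]$values * 70 + layers[[2]]$values * 210 +
    layers[[3]]$values * 720
  expect_equal(agg$smnear$values + agg$smsub$values, total, tolerance = 1e-9)

  expect_error(aggregate_soil_layers(layers, depths, 0.10), "boundary")
  expect_error(aggregate_soil_layers(layers, list(c(0, 0.07), c(0.10, 0.28),
                                                  c(0.28, 1.0)), 0.07),
               "contiguous")
  bad <- layers; bad[[1]]$units <- "mm"
  expect_error(aggregate_soil_layers(bad, depths, 0.07), "m3/m3")
})

test_that("growing-season mask uses strict thresholds", {
  dims <- c(1, 1, 3)
  temp <- mk_field(array(c(10, 5, 20), dims), "degC")
  lai <- mk_field(array(c(1.0, 1.0, 0.3), dims), "m2/m2")
  m <- growing_season_mask(temp, lai)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE))

  vi <- mk_field(array(c(-0.1, 1, 1), dims), "1")
  m2 <- growing_season_mask(temp, lai, vegetation_index_fields = list(vi))
  expect_identical(as.vector(m2), c(FALSE, FALSE, FALSE))
})

test_that("deseasonalizing removes the mean annual cycle exactly", {
  cyc <- rep(sin(2 * pi * (1:12) / 12), 2)
  f <- mk_field(array(rep(cyc, 4), c(24, 2, 2)), "mm")
  a <- deseasonalize(f)
  expect_true(all(abs(a$values) < 1e-12))

  const <- mk_field(array(3.7, c(24, 2, 2)), "mm")
  expect_true(all(abs(deseasonalize(const)$values) < 1e-12))

  set.seed(11)
  noisy <- mk_field(array(rnorm(36 * 4), c(36, 2, 2)), "mm")
  an <- deseasonalize(noisy)
  mon <- as.integer(format(an$time, "%m"))
  for (m in 1:12)
    expect_lt(max(abs(apply(an$values[mon == m, , , drop = FALSE], c(2, 3),
                            mean))), 1e-10)
  # idempotence: a second pass changes nothing
  an2 <- deseasonalize(an)
  expect_lt(max(abs(an2$values - an$values)), 1e-8)
})

test_that("deseasonalize flags scarce months instead of erroring", {
  vals <- array(rnorm(24 * 1 * 1), c(24, 1, 1))
  mask <- array(TRUE, c(24, 1, 1))
  mask[c(1, 13), 1, 1] <- FALSE          # january appears 0 times valid
  mask[c(2), 1, 1] <- FALSE              # february appears once
  f <- mk_field(vals, "mm")
  a <- deseasonalize(f, mask)
  mon <- as.integer(format(f$time, "%m"))
  expect_true(all(is.na(a$values[mon <= 2, 1, 1])))
  expect_true(all(!is.na(a$values[mon > 2, 1, 1])))

  all_missing <- mk_field(array(NA_real_, c(24, 1, 1)), "mm")
  expect_silent(am <- deseasonalize(all_missing))
  expect_true(all(is.na(am$values)))
})

test_that("LOWESS de-trending removes linear and constant signals", {
  x <- seq_len(120)
  lin <- 0.02 * x + 1
  r <- detrend_lowess(lin)
  expect_lt(max(abs(r)), 1e-6 * diff(range(lin)))
  expect_lt(max(abs(detrend_lowess(rep(2, 60)))), 1e-9)
  expect_true(all(is.na(detrend_lowess(rnorm(9)))))
  expect_error(detrend_lowess(rnorm(20), span = 0), "span")

  # linear trend + AR(1) noise: residual trend is statistically zero
  set.seed(21)
  n <- 300
  e <- as.numeric(arima.sim(list(ar = 0.5), n))
  y <- 0.05 * seq_len(n) + e
  res <- detrend_lowess(y)
  fit <- summary(lm(res ~ seq_len(n)))$coefficients
  expect_lt(abs(fit[2, 1] / fit[2, 2]), 2)
})

test_that("the anomaly pipeline removes seasonality plus trend completely", {
  cfg <- synth_config(n_lat = 3, n_lon = 3, start_year = 1990, end_year = 2009,
                      base_sensitivity_sub = 0, base_sensitivity_near = 0,
                      temp_effect = 0, noise_sd = 0)
  cfg$anomaly_sd[] <- 0   # deterministic: climatology + linear drift only
  ds <- generate_dataset(cfg)
  sm <- aggregate_soil_layers(ds$fields$sm_layers,
                              attr(ds$fields$sm_layers, "depths"), 0.07)
  an <- build_anomaly_dataset(ds$fields$lai, sm$smnear, sm$smsub,
                              ds$fields$temp, ds$fields$precip, ds$fields$vpd,
                              ds$fields$rad)
  amp <- cfg$seasonal_amplitudes
  scale <- c(lai = amp[["lai"]], smsub = 1000 * amp[["smsub_vol"]],
             temp = amp[["temp"]], precip = amp[["precip"]])
  for (v in names(scale)) {
    vals <- an[[v]]$values[an$valid_mask]
    expect_lt(max(abs(vals), na.rm = TRUE), 0.05 * scale[[v]])
  }
  expect_identical(an$valid_mask,
                   growing_season_mask(ds$fields$temp, ds$fields$lai))
})

test_that("imposed anomaly signals survive preprocessing almost unchanged", {
  cfg <- synth_config(n_lat = 3, n_lon = 3, start_year = 1982, end_year = 2017,
                      base_sensitivity_sub = 0.5, noise_sd = 0)
  ds <- generate_dataset(cfg)
  sm <- aggregate_soil_layers(ds$fields$sm_layers,
                              attr(ds$fields$sm_layers, "depths"), 0.07)
  an <- build_anomaly_dataset(ds$fields$lai, sm$smnear, sm$smsub,
                              ds$fields$temp, ds$fields$precip, ds$fields$vpd,
                              ds$fields$rad)
  for (i in 1:3) for (j in 1:3) {
    ok <- an$valid_mask[, i, j] & !is.na(an$lai$values[, i, j])
    expect_gt(cor(an$lai$values[ok, i, j],
                  ds$truth$components$lai_signal[ok, i, j]), 0.95)
    expect_gt(cor(an$smsub$values[ok, i, j],
                  ds$truth$components$smsub_anom_mm[ok, i, j]), 0.95)
  }
  # anomalies are centered over valid steps
  m <- an$lai$values[an$valid_mask]
  expect_lt(abs(mean(m, na.rm = TRUE)), 0.05 * sd(m, na.rm = TRUE))
})

test_that("deseasonalize and detrend nearly commute on AR(1) data", {
  set.seed(31)
  n <- 240
  vals <- array(as.numeric(arima.sim(list(ar = 0.6), n)) +
                  rep(2 * sin(2 * pi * (1:12) / 12), length.out = n) +
                  0.01 * seq_len(n), c(n, 1, 1))
  f <- mk_field(vals, "mm")
  a1 <- deseasonalize(f)$values[, 1, 1]
  r1 <- detrend_lowess(a1)
  r2v <- detrend_lowess(f$values[, 1, 1])
  f2 <- f; f2$values[, 1, 1] <- r2v
  r2 <- deseasonalize(f2)$values[, 1, 1]
  expect_gt(cor(r1, r2, use = "complete.obs"), 0.95)
})
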