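mk_trend_field <- function(vals, n_time = 144) {
  d <- c(n_time, dim(vals))
  arr <- array(0, d)
  for (t in seq_len(n_time)) arr[t, , ] <- vals * (t - 1) / 12  # vals per year
  time <- seq(as.Date("2000-01-01"), by = "month", length.out = n_time)
  grid_field(arr, "mm", time, 40 + 0.5 * seq_len(d[2]),
             10 + 0.5 * seq_len(d[3]), "x")
}

test_that("predictor trends recover exact linear drifts", {
  delta <- matrix(c(0.5, -1, 0, 2), 2, 2)
  f <- mk_trend_field(delta)
  mask <- array(TRUE, dim(f$values))
  tr <- predictor_trends(f, mask)
  expect_equal(tr, delta, tolerance = 1e-10)

  # constant field
  cf <- f; cf$values[] <- 7
  expect_equal(predictor_trends(cf, mask), matrix(0, 2, 2))

  # annual-mean invariance to an added seasonal cycle
  seas <- f
  seas$values <- f$values + rep(3 * sin(2 * pi * (1:12) / 12),
                                length.out = dim(f$values)[1])
  expect_equal(predictor_trends(seas, mask), tr, tolerance = 1e-10)

  # too few years flagged missing
  short <- mk_trend_field(delta, n_time = 60)
  expect_true(all(is.na(predictor_trends(short, array(TRUE, dim(short$values))))))
})

synth_attribution_inputs <- function(n_side = 23, seed = 22, pure_noise = FALSE,
                                     k = 0.8) {
  set.seed(seed)
  preds <- list(
    overall_sensitivity = matrix(runif(n_side^2, 0, 1), n_side),
    precip_trend = matrix(rnorm(n_side^2), n_side),
    smnear_trend = matrix(rnorm(n_side^2), n_side),
    smsub_trend = matrix(rnorm(n_side^2), n_side),
    temp_trend = matrix(rnorm(n_side^2), n_side),
    rad_trend = matrix(rnorm(n_side^2), n_side),
    vpd_trend = matrix(rnorm(n_side^2), n_side),
    nontree_fraction = matrix(runif(n_side^2), n_side))
  target <- if (pure_noise) matrix(rnorm(n_side^2), n_side)
  else -k * preds$precip_trend + matrix(rnorm(n_side^2, 0, 0.05), n_side)
  list(target = target, preds = preds)
}

test_that("attribution ranks the true generative control first", {
  inp <- synth_attribution_inputs()
  att <- attribute_trends(inp$target, inp$preds)
  expect_identical(att$importance$predictor[1], "precip_trend")
  share <- att$importance$mean_abs_shap[1] / sum(att$importance$mean_abs_shap)
  expect_gte(share, 0.5)
  # SHAP additivity for the attribution model
  expect_equal(rowSums(att$shap) + att$base,
               unname(predict(att$model,
                              as.matrix(att$data[, -1]))),
               tolerance = 1e-6)
})

test_that("attribution ranking is stable across seeds", {
  inp <- synth_attribution_inputs()
  top <- vapply(1:5, function(s) {
    cfg <- rf_config(random_state = s)
    attribute_trends(inp$target, inp$preds, cfg)$importance$predictor[1]
  }, character(1))
  expect_gte(sum(top == "precip_trend"), 4)
})

test_that("pure-noise targets yield no dominant predictor", {
  hits <- 0L
  for (s in 1:20) {
    inp <- synth_attribution_inputs(n_side = 12, seed = 100 + s,
                                    pure_noise = TRUE)
    att <- attribute_trends(inp$target, inp$preds,
                            rf_config(random_state = s), min_rows = 50)
    imp <- att$importance$mean_abs_shap
    if (max(imp) <= 2 * mean(imp)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("duplicated predictors share the original's attribution mass", {
  inp <- synth_attribution_inputs(seed = 23)
  att1 <- attribute_trends(inp$target, inp$preds)
  single <- att1$importance$mean_abs_shap[
    att1$importance$predictor == "precip_trend"]
  dup <- c(inp$preds, list(precip_trend_copy = inp$preds$precip_trend))
  att2 <- attribute_trends(inp$target, dup)
  pair <- sum(att2$importance$mean_abs_shap[
    att2$importance$predictor %in% c("precip_trend", "precip_trend_copy")])
  expect_lt(abs(pair - single) / single, 0.3)
})

test_that("attribution input contracts are enforced", {
  inp <- synth_attribution_inputs(n_side = 6)
  expect_error(attribute_trends(inp$target, inp$preds), "at least 50")
  inp2 <- synth_attribution_inputs()
  inp2$target[] <- 1
  expect_error(attribute_trends(inp2$target, inp2$preds), "constant")
})

test_that("top-two grouping partitions cells and tracks the construction", {
  inp <- synth_attribution_inputs(seed = 24)
  g1 <- group_by_top2(inp$target, inp$preds$precip_trend,
                      inp$preds$overall_sensitivity, bins1 = 1, bins2 = 1)
  expect_equal(g1$median[1, 1], median(inp$target))
  expect_equal(sum(g1$count), length(inp$target))

  g <- group_by_top2(inp$target, inp$preds$precip_trend,
                     inp$preds$overall_sensitivity, bins1 = 4, bins2 = 4)
  expect_equal(sum(g$count), length(inp$target))
  # target = -k * precip_trend (+tiny noise): medians decrease along axis 1
  for (col in 1:4) {
    m <- g$median[, col]
    expect_true(all(diff(m[!is.na(m)]) < 0))
  }
})
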