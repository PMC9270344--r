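test_that("theil_sen matches the brute-force all-pairs median", {
  set.seed(9)
  for (k in 1:8) {
    n <- sample(5:50, 1)
    x <- round(rnorm(n), 1)            # duplicates exercise the x_i = x_j rule
    y <- 0.7 * x + rnorm(n)
    if (all(x == x[1])) next
    expect_equal(theil_sen(x, y)$slope, theil_sen_bruteforce(x, y))
  }
})

test_that("theil_sen handles canonical cases and errors", {
  expect_equal(theil_sen(1:5, 2 * (1:5))$slope, 2)
  expect_lt(theil_sen(1:5, 2 * (1:5))$p_value, 0.05)
  # pairwise slopes {1, 3, 2} -> median 2
  expect_equal(theil_sen(c(0, 1, 2), c(0, 1, 4))$slope, 2)
  ts <- theil_sen(1:10, rep(3, 10))
  expect_equal(ts$slope, 0)
  expect_equal(ts$p_value, 1)
  expect_error(theil_sen(c(1, 2), c(1, 2)), "3 finite")
  expect_error(theil_sen(rep(1, 5), 1:5), "identical")
})

test_that("neighborhood pooling counts valid rows cell by cell", {
  an <- make_anomaly_dataset(n_time = 100, n_lat = 4, n_lon = 4)
  expect_identical(nrow(pool_neighborhood(an, 2, 2)), 900L)
  expect_identical(nrow(pool_neighborhood(an, 1, 1)), 400L)   # corner
  expect_identical(nrow(pool_neighborhood(an, 1, 2)), 600L)   # edge
  expect_error(pool_neighborhood(an, 9, 1), "outside")

  an$valid_mask[] <- FALSE
  expect_identical(nrow(pool_neighborhood(an, 2, 2)), 0L)

  # block restriction
  an2 <- make_anomaly_dataset(n_time = 100, n_lat = 4, n_lon = 4)
  expect_identical(nrow(pool_neighborhood(an2, 2, 2, time_idx = 1:10)), 90L)

  # core flag marks exactly the core cell's rows
  tab <- pool_neighborhood(an2, 2, 2)
  expect_identical(sum(tab$core), 100L)
})

test_that("minimum-sample rules are strict and distinct from the OOB gate", {
  set.seed(10)
  mk_tab <- function(n, signal = TRUE) {
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c("smnear", "smsub", "temp", "precip",
                                        "vpd", "rad")))
    y <- if (signal) 0.6 * X[, "smsub"] + rnorm(n, 0, 0.1) else rnorm(n)
    data.frame(X, lai = y)
  }
  cfg <- rf_config()
  # exactly 50 rows: "more than 50" is strict
  expect_identical(fit_gated_model(mk_tab(50), cfg)$status, "insufficient")
  expect_identical(fit_gated_model(mk_tab(51), cfg)$status, "ok")
  expect_identical(fit_gated_model(mk_tab(15), cfg, cfg$min_points_block)$status,
                   "insufficient")
  expect_null(fit_gated_model(mk_tab(50), cfg)$model)

  # informative signal is retained with positive OOB skill
  fit <- fit_gated_model(mk_tab(500), cfg)
  expect_identical(fit$status, "ok")
  expect_gt(fit$oob_r2, 0)
})

test_that("calendar blocks reproduce the analysis period structure", {
  time <- month_seq_ext(1982, 2017)
  b3 <- year_blocks(time, 3)
  expect_length(b3$index, 12)
  expect_equal(b3$bounds$first, seq(1982, 2015, by = 3))
  expect_equal(b3$bounds$last, seq(1984, 2017, by = 3))
  expect_equal(b3$centers[1], 1983)
  expect_identical(length(b3$index[[1]]), 36L)

  expect_warning(b5 <- year_blocks(time, 5), "dropped")
  expect_length(b5$index, 7)
  expect_equal(b5$bounds$first, seq(1982, 2012, by = 5))
  expect_equal(b5$bounds$last[7], 2016)
})

test_that("sensitivity maps are reproducible and order-independent", {
  an <- make_anomaly_dataset(n_time = 120, n_lat = 3, n_lon = 3, seed = 12,
                             lai_fun = function(f)
                               0.5 * f$smsub$values + array(rnorm(120 * 9, 0, 0.2),
                                                            c(120, 3, 3)))
  cells <- rbind(c(2, 2), c(1, 3))
  m1 <- overall_sensitivity(an, "sub", cells = cells)
  m2 <- overall_sensitivity(an, "sub", cells = cells[2:1, , drop = FALSE])
  expect_identical(m1$slope, m2$slope)
  expect_identical(m1$p_value, m2$p_value)
  m3 <- overall_sensitivity(an, "sub", cells = cells)
  expect_identical(m1$slope, m3$slope)
  expect_identical(m1$status[2, 2], "ok")
  expect_gt(m1$slope[2, 2], 0.3)
})

test_that("ensemble averaging combines member maps cell-wise", {
  base <- structure(list(slope = matrix(1, 2, 2), p_value = matrix(0.05, 2, 2),
                         oob_r2 = matrix(0.5, 2, 2),
                         n_samples = matrix(100, 2, 2)),
                    class = "sensitivity_map")
  other <- base
  other$slope <- matrix(c(3, NA, 3, 3), 2, 2)
  em <- ensemble_mean(list(base, other))
  expect_equal(em$slope, matrix(c(2, 1, 2, 2), 2, 2))
})
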