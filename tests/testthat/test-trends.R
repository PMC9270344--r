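test_that("mann_kendall matches pair enumeration with ties", {
  set.seed(14)
  for (k in 1:10) {
    n <- sample(4:30, 1)
    y <- sample(round(rnorm(n), if (k %% 2) 0 else 2))  # coarse rounding => ties
    mk <- mann_kendall(y)
    bf <- mann_kendall_bruteforce(y)
    expect_equal(mk$S, bf$S)
    expect_equal(mk$var_S, bf$var_S)
  }
})

test_that("mann_kendall reproduces canonical examples", {
  mk <- mann_kendall(1:10)
  expect_equal(mk$S, 45)
  expect_lt(mk$p_value, 0.01)
  expect_equal(mk$sen_slope, 1)

  const <- mann_kendall(rep(2, 8))
  expect_equal(const$S, 0)
  expect_equal(const$p_value, 1)

  expect_equal(mann_kendall(c(1, 3, 2, 4))$S, 4)
  expect_error(mann_kendall(c(1, 2, 3)), "4 finite")

  # Sen slope is the all-pairs median against time
  set.seed(15)
  y <- cumsum(rnorm(12))
  slopes <- c()
  for (i in 1:11) for (j in (i + 1):12)
    slopes <- c(slopes, (y[j] - y[i]) / (j - i))
  expect_equal(mann_kendall(y)$sen_slope, median(slopes))
})

fake_blocks <- function(slope_arr, valid = NULL, centers = NULL,
                        lat = NULL, lon = NULL) {
  d <- dim(slope_arr)
  structure(list(slope = slope_arr,
                 p_value = array(0.01, d),
                 valid = if (is.null(valid)) array(TRUE, d) else valid,
                 block_centers = if (is.null(centers))
                   seq(1983, by = 3, length.out = d[1]) else centers,
                 lat = if (is.null(lat)) 40 + 0.5 * seq_len(d[2]) else lat,
                 lon = if (is.null(lon)) 10 + 0.5 * seq_len(d[3]) else lon,
                 block_years = 3L, alpha = 0.1),
            class = "block_sensitivity")
}

test_that("trend_map honors the controlled mask and block minimum", {
  set.seed(16)
  sl <- array(rnorm(12 * 2 * 2), c(12, 2, 2))
  sl[, 1, 1] <- seq(0.1, 1.2, by = 0.1)      # clean increase
  blocks <- fake_blocks(sl)
  blocks$valid[5:12, 2, 2] <- FALSE          # only 4 valid left
  blocks$valid[2:12, 2, 1] <- FALSE          # 1 valid: insufficient
  ctrl <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  tm <- trend_map(blocks, ctrl)
  expect_identical(tm$status[1, 2], "excluded")
  expect_true(is.na(tm$sen_slope[1, 2]))
  expect_identical(tm$status[2, 1], "insufficient")
  expect_identical(tm$status[1, 1], "ok")
  expect_gt(tm$sen_slope[1, 1], 0)
  expect_lt(tm$mk_p[1, 1], 0.1)
  expect_identical(tm$n_blocks[2, 2], 4L)
})

test_that("global series re-bases to the first block and detects drift", {
  # single cell: series equals that cell's blocks re-based to zero
  sl <- array(c(2, 3, 5, 4, 6, 7, 8, 9, 10, 11, 12, 13), c(12, 1, 1))
  g1 <- global_series(fake_blocks(sl), matrix(TRUE, 1, 1))
  expect_equal(g1$values, as.vector(sl) - 2)

  # uniform drift everywhere: aggregate is 0, d, 2d, ...
  nb <- 12
  sl2 <- array(rep(0.1 * (seq_len(nb) - 1), 4), c(nb, 2, 2))
  g2 <- global_series(fake_blocks(sl2), matrix(TRUE, 2, 2))
  expect_equal(g2$values, 0.1 * (seq_len(nb) - 1))
  expect_lt(g2$mk$p_value, 0.01)

  expect_error(global_series(fake_blocks(sl2), matrix(FALSE, 2, 2)), "empty")
})

test_that("area fractions weight by cosine latitude and partition", {
  mk_trend <- function(slope, p, lat) {
    structure(list(sen_slope = slope, mk_p = p,
                   n_blocks = matrix(12L, nrow(slope), ncol(slope)),
                   status = matrix("ok", nrow(slope), ncol(slope)),
                   lat = lat, lon = seq_len(ncol(slope)), alpha = 0.1,
                   block_years = 3L), class = "trend_map")
  }
  eq <- mk_trend(matrix(c(1, -1, 2, -2), 2, 2), matrix(0.5, 2, 2), c(0, 0))
  fr <- area_fractions(eq)
  expect_equal(fr$increasing, 0.5)
  expect_equal(fr$decreasing, 0.5)
  expect_equal(fr$significant_increasing, 0)
  expect_equal(fr$increasing + fr$decreasing + fr$remaining, 1)

  allpos <- mk_trend(matrix(1, 2, 2), matrix(0.01, 2, 2), c(0, 0))
  fr2 <- area_fractions(allpos)
  expect_equal(fr2$increasing, 1)
  expect_equal(fr2$significant_increasing, 1)

  # two latitude rows, only the equatorial row increasing
  two <- mk_trend(matrix(c(1, -1), 2, 1), matrix(0.5, 2, 1), c(0, 60))
  fr3 <- area_fractions(two)
  expect_equal(fr3$increasing, cos(0) / (cos(0) + cos(pi / 3)), tolerance = 1e-12)
})

test_that("response function bins significant cells against mean moisture", {
  n <- 10L
  sens <- structure(list(slope = matrix(0.4, n, n),
                         p_value = matrix(0.001, n, n)),
                    class = "sensitivity_map")
  msm <- matrix(seq(10, 100, length.out = n * n), n, n)
  flat <- response_function(sens, msm, bins = 5)
  expect_true(all(flat$median == 0.4))
  expect_true(all(flat$q75 - flat$q25 == 0))
  expect_identical(sum(flat$n), n * n)

  # slope = 1/mean_sm: binned medians decrease monotonically
  sens2 <- sens
  sens2$slope <- 1 / msm
  dec <- response_function(sens2, msm, bins = 5)
  expect_true(all(diff(dec$median) < 0))

  # non-significant cells are excluded from the bin weights
  sens3 <- sens
  sens3$p_value[1:5, 1] <- 0.5
  expect_identical(sum(response_function(sens3, msm, bins = 5)$n), n * n - 5L)
})

test_that("regime comparison returns exact diffs and null correlations", {
  set.seed(18)
  a <- matrix(rnorm(400), 20, 20)
  regimes <- list(labels = matrix(rep(1:4, each = 100), 20, 20))
  same <- regime_compare(a, a, regimes)
  expect_true(all(same$mean_diff == 0))
  expect_equal(same$correlation, rep(1, 4))

  shifted <- regime_compare(a, a + 3, regimes)
  expect_true(all(abs(shifted$mean_diff + 3) < 1e-12))
  expect_equal(shifted$correlation, rep(1, 4))

  b <- matrix(rnorm(400), 20, 20)   # independent noise
  indep <- regime_compare(a, b, regimes)
  expect_true(all(abs(indep$correlation) < 0.2))
  expect_true(all(indep$n == 100))
})

test_that("null per-cell trend significance stays at its nominal level", {
  set.seed(19)
  n_cells <- 200
  p <- vapply(seq_len(n_cells), function(i)
    mann_kendall(rnorm(12))$p_value, numeric(1))
  frac <- mean(p < 0.1)
  expect_lte(frac, 0.2)   # binomial upper bound around the nominal 0.1
  expect_gte(frac, 0.02)
})
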