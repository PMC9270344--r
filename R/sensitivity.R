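PREDICTORS <- c("smnear", "smsub", "temp", "precip", "vpd", "rad")

#' Random-forest configuration for per-cell sensitivity models
#'
#' Hyperparameters of the bagged tree ensembles: 100 trees, 30% of features
#' tried per split, a fixed random state, and the minimum-sample rules (more
#' than 50 pooled points for the overall model, more than 15 per temporal
#' block; strict inequalities). `min_oob` is the out-of-bag skill gate:
#' cells whose model does not beat the training mean (OOB R-squared <=
#' `min_oob`) are discarded. `nodesize` is the minimum leaf size of the
#' regression trees.
#'
#' @param n_trees number of trees (default 100).
#' @param max_features_fraction fraction of predictors tried per split
#'   (default 0.30; `mtry = max(1, round(fraction * p))`, i.e. 2 of the 6
#'   hydro-climate predictors).
#' @param random_state base seed (default 42); per-cell seeds are derived
#'   deterministically so results are independent of evaluation order.
#' @param min_points_overall,min_points_block strict minimum sample counts.
#' @param min_oob out-of-bag R-squared gate (default 0).
#' @param nodesize minimum leaf size (default 25).
#' @param dependence_rows `"pooled"` (SHAP dependence over all pooled training
#'   rows, the default) or `"core"` (core-cell rows only).
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, max_features_fraction = 0.30,
                      random_state = 42L, min_points_overall = 50L,
                      min_points_block = 15L, min_oob = 0,
                      nodesize = 25L, dependence_rows = c("pooled", "core")) {
  stopifnot(n_trees >= 1L, max_features_fraction > 0, max_features_fraction <= 1,
            min_points_overall >= 2L, min_points_block >= 2L, nodesize >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_features_fraction = max_features_fraction,
                 random_state = as.integer(random_state),
                 min_points_overall = as.integer(min_points_overall),
                 min_points_block = as.integer(min_points_block),
                 min_oob = min_oob, nodesize = as.integer(nodesize),
                 dependence_rows = match.arg(dependence_rows)),
            class = "rf_config")
}

# deterministic per-cell (and per-block) seed below 2^31
cell_seed <- function(config, i, j, block = 0L) {
  (config$random_state * 1000003L +
     ((i - 1L) * 512L + (j - 1L)) * 7919L + block * 104729L) %% 2147483647L
}

#' Pool the 3x3 neighborhood of a grid cell into a training table
#'
#' Collects all valid (growing-season, non-missing) time steps of the core
#' cell and its surrounding cells into one table of the six hydro-climate
#' predictors and the LAI-anomaly target. Boundary cells use the neighbors
#' that exist; an optional time subset restricts rows to a temporal block.
#'
#' @param anomalies an `anomaly_dataset`.
#' @param i,j core-cell indices (lat, lon).
#' @param window odd neighborhood width (default 3).
#' @param time_idx optional integer subset of time steps.
#' @return data.frame with columns `smnear`, `smsub`, `temp`, `precip`,
#'   `vpd`, `rad`, `lai`, and a logical `core` flag.
#' @export
pool_neighborhood <- function(anomalies, i, j, window = 3L, time_idx = NULL) {
  d <- dim(anomalies$valid_mask)
  if (i < 1L || i > d[2] || j < 1L || j > d[3]) stop("cell outside grid", call. = FALSE)
  h <- (window - 1L) %/% 2L
  ii <- max(1L, i - h):min(d[2], i + h)
  jj <- max(1L, j - h):min(d[3], j + h)
  tt <- if (is.null(time_idx)) seq_len(d[1]) else time_idx
  vars <- c(PREDICTORS, "lai")
  rows <- vector("list", length(ii) * length(jj))
  n <- 0L
  for (ci in ii) for (cj in jj) {
    ok <- anomalies$valid_mask[tt, ci, cj]
    cols <- lapply(vars, function(v) anomalies[[v]]$values[tt, ci, cj][ok])
    tab <- as.data.frame(cols, col.names = vars)
    tab <- tab[stats::complete.cases(tab), , drop = FALSE]
    if (nrow(tab)) {
      tab$core <- ci == i && cj == j
      n <- n + 1L
      rows[[n]] <- tab
    }
  }
  if (n == 0L)
    return(cbind(as.data.frame(sapply(vars, function(v) numeric(0))),
                 core = logical(0)))
  do.call(rbind, rows[seq_len(n)])
}

#' Fit the gated random-forest model for one training table
#'
#' Fits the bagged tree ensemble of LAI anomalies on the six predictors and
#' applies the two removal rules: tables with `min_points` rows or fewer are
#' flagged `"insufficient"` (never fitted); fitted models whose out-of-bag
#' R-squared does not exceed `min_oob` are flagged `"gated"`. OOB R-squared is
#' `1 - SSE_oob / SST`, i.e. skill relative to predicting the training mean.
#'
#' @param table training table from [pool_neighborhood()].
#' @param config an [rf_config()].
#' @param min_points strict minimum rows (defaults to
#'   `config$min_points_overall`).
#' @param seed seed set immediately before fitting (defaults to
#'   `config$random_state`).
#' @return list with `status` (`"ok"`, `"gated"`, or `"insufficient"`),
#'   `model`, `oob_r2`, `n` and the table.
#' @export
fit_gated_model <- function(table, config = rf_config(),
                            min_points = config$min_points_overall,
                            seed = config$random_state) {
  n <- nrow(table)
  if (n <= min_points)
    return(list(status = "insufficient", model = NULL, oob_r2 = NA_real_,
                n = n, table = table))
  x <- as.matrix(table[, PREDICTORS, drop = FALSE])
  y <- table$lai
  mtry <- max(1L, round(config$max_features_fraction * length(PREDICTORS)))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = config$n_trees, mtry = mtry,
                                   nodesize = config$nodesize,
                                   keep.forest = TRUE, keep.inbag = TRUE)
  oob <- rf$predicted
  ok <- !is.na(oob)
  oob_r2 <- 1 - sum((y[ok] - oob[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
  status <- if (oob_r2 <= config$min_oob) "gated" else "ok"
  list(status = status, model = rf, oob_r2 = oob_r2, n = n, table = table)
}

#' SHAP dependence of the LAI model on one soil-moisture feature
#'
#' Pairs each training row's soil-moisture anomaly value with its exact
#' TreeSHAP attribution, isolating the marginal contribution of that layer to
#' the modeled LAI anomaly.
#'
#' @param fit result of [fit_gated_model()] with `status == "ok"` (or
#'   `"gated"`; the caller decides whether to use it).
#' @param feature `"smnear"` or `"smsub"`.
#' @param rows `"pooled"` (all training rows) or `"core"` (core-cell rows).
#' @return list of class `shap_dependence` with equal-length vectors `x`
#'   (soil-moisture anomaly, mm) and `shap` (LAI-anomaly units), plus `base`.
#' @export
shap_dependence <- function(fit, feature = c("smsub", "smnear"),
                            rows = c("pooled", "core")) {
  feature <- match.arg(feature)
  rows <- match.arg(rows)
  if (is.null(fit$model)) stop("no fitted model in `fit`", call. = FALSE)
  x_train <- as.matrix(fit$table[, PREDICTORS, drop = FALSE])
  sv <- shap_values(fit$model, x_train)
  keep <- if (rows == "core" && !is.null(fit$table$core)) fit$table$core
  else rep(TRUE, nrow(x_train))
  structure(list(x = x_train[keep, feature], shap = sv$phi[keep, feature],
                 base = sv$base, feature = feature, phi = sv$phi[keep, , drop = FALSE]),
            class = "shap_dependence")
}

#' Theil-Sen robust regression
#'
#' Slope = median of all pairwise slopes `(y_j - y_i) / (x_j - x_i)` over pairs
#' with distinct x; intercept = `median(y) - slope * median(x)`. Significance
#' is the two-sided Kendall rank-association test between x and y (normal
#' approximation with tie correction).
#'
#' @param x,y numeric vectors (pairs with missing values are dropped; at least
#'   3 finite pairs required).
#' @return list with `slope`, `intercept`, `p_value`, `n`.
#' @export
theil_sen <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("theil_sen needs at least 3 finite pairs", call. = FALSE)
  if (all(x == x[1L])) stop("all x identical: slope undefined", call. = FALSE)
  dx <- outer(x, x, "-")
  lower <- lower.tri(dx)
  dxl <- dx[lower]
  dyl <- outer(y, y, "-")[lower]
  slope <- median(dyl[dxl != 0] / dxl[dxl != 0])
  p <- if (all(y == y[1L])) 1 else
    suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE)$p.value)
  list(slope = slope, intercept = median(y) - slope * median(x),
       p_value = p, n = n)
}

sens_template <- function(anomalies) {
  d <- dim(anomalies$valid_mask)
  m <- matrix(NA_real_, d[2], d[3])
  list(slope = m, p_value = m, oob_r2 = m,
       n_samples = matrix(NA_integer_, d[2], d[3]),
       status = matrix("missing", d[2], d[3]))
}

#' Per-grid-cell overall LAI sensitivity to a soil-moisture layer
#'
#' For every grid cell: pool the 3x3 neighborhood over the full period, fit
#' the gated random forest, compute the SHAP dependence for the chosen layer,
#' and summarize it as a Theil-Sen slope with a two-sided Kendall p-value.
#'
#' @param anomalies an `anomaly_dataset`.
#' @param layer `"sub"` or `"near"` soil moisture.
#' @param config an [rf_config()].
#' @param window pooling width (default 3).
#' @param cells optional 2-column matrix of (i, j) indices to restrict
#'   computation.
#' @return object of class `sensitivity_map`: matrices `slope` (LAI anomaly
#'   per mm), `p_value`, `oob_r2`, `n_samples`, a per-cell `status`
#'   (`"ok"`, `"gated"`, `"insufficient"`, `"missing"`), coordinates, `layer`
#'   and `config`.
#' @export
overall_sensitivity <- function(anomalies, layer = c("sub", "near"),
                                config = rf_config(), window = 3L,
                                cells = NULL) {
  layer <- match.arg(layer)
  feature <- paste0("sm", layer)
  out <- sens_template(anomalies)
  d <- dim(anomalies$valid_mask)
  if (is.null(cells))
    cells <- as.matrix(expand.grid(i = seq_len(d[2]), j = seq_len(d[3])))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1L]; j <- cells[r, 2L]
    tab <- pool_neighborhood(anomalies, i, j, window)
    fit <- fit_gated_model(tab, config, config$min_points_overall,
                           seed = cell_seed(config, i, j))
    out$n_samples[i, j] <- fit$n
    out$status[i, j] <- fit$status
    if (fit$status == "insufficient") next
    out$oob_r2[i, j] <- fit$oob_r2
    if (fit$status != "ok") next
    dep <- shap_dependence(fit, feature, rows = config$dependence_rows)
    if (length(unique(dep$x)) < 2L) next  # degenerate moisture column
    ts <- theil_sen(dep$x, dep$shap)
    out$slope[i, j] <- ts$slope
    out$p_value[i, j] <- ts$p_value
  }
  structure(c(out, list(layer = layer, lat = anomalies$lat, lon = anomalies$lon,
                        config = config, window = window)),
            class = "sensitivity_map")
}

#' Split a monthly calendar into consecutive year blocks
#'
#' @param time `Date` vector of month starts.
#' @param block_years block length in years (default 3).
#' @return list with `index` (list of time-index vectors per block),
#'   `centers` (decimal center year per block), `bounds` (data.frame of first
#'   and last calendar year per block). A trailing partial block is dropped
#'   with a warning.
#' @export
year_blocks <- function(time, block_years = 3L) {
  yrs <- year_of(time)
  y0 <- min(yrs)
  n_complete <- (max(yrs) - y0 + 1L) %/% block_years
  if ((max(yrs) - y0 + 1L) %% block_years != 0L)
    warning(sprintf("trailing partial block (%d year(s)) dropped",
                    (max(yrs) - y0 + 1L) %% block_years), call. = FALSE)
  if (n_complete < 1L) stop("period shorter than one block", call. = FALSE)
  first <- y0 + block_years * (seq_len(n_complete) - 1L)
  last <- first + block_years - 1L
  idx <- lapply(seq_len(n_complete), function(b) which(yrs >= first[b] & yrs <= last[b]))
  list(index = idx, centers = (first + last) / 2,
       bounds = data.frame(first = first, last = last))
}

#' Block-wise LAI sensitivity to a soil-moisture layer
#'
#' Recomputes the pool / gate / SHAP / Theil-Sen chain on consecutive
#' multi-year blocks (default 3 years) of the record, re-gating each block's
#' model on its own out-of-bag skill. A block estimate is valid only when the
#' model passes the gate, has more than `min_points_block` rows, and the
#' Theil-Sen p-value is below `alpha` (estimates with p >= alpha are removed).
#'
#' @param anomalies an `anomaly_dataset`.
#' @param layer `"sub"` or `"near"`.
#' @param config an [rf_config()].
#' @param block_years block length (3 by default; 5 for the robustness
#'   variant).
#' @param alpha per-block significance threshold (default 0.1).
#' @param window pooling width.
#' @param cells optional cell subset as in [overall_sensitivity()].
#' @return object of class `block_sensitivity`: arrays `slope`, `p_value`,
#'   `valid` of dimension `(block, lat, lon)`, `block_centers`,
#'   `block_bounds`, and metadata.
#' @export
block_sensitivity <- function(anomalies, layer = c("sub", "near"),
                              config = rf_config(), block_years = 3L,
                              alpha = 0.1, window = 3L, cells = NULL) {
  layer <- match.arg(layer)
  feature <- paste0("sm", layer)
  blocks <- year_blocks(anomalies$time, block_years)
  nb <- length(blocks$index)
  d <- dim(anomalies$valid_mask)
  slope <- array(NA_real_, c(nb, d[2], d[3]))
  pval <- array(NA_real_, c(nb, d[2], d[3]))
  valid <- array(FALSE, c(nb, d[2], d[3]))
  if (is.null(cells))
    cells <- as.matrix(expand.grid(i = seq_len(d[2]), j = seq_len(d[3])))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1L]; j <- cells[r, 2L]
    for (b in seq_len(nb)) {
      tab <- pool_neighborhood(anomalies, i, j, window, blocks$index[[b]])
      fit <- fit_gated_model(tab, config, config$min_points_block,
                             seed = cell_seed(config, i, j, b))
      if (fit$status != "ok") next
      dep <- shap_dependence(fit, feature, rows = config$dependence_rows)
      if (length(unique(dep$x)) < 2L) next
      ts <- theil_sen(dep$x, dep$shap)
      slope[b, i, j] <- ts$slope
      pval[b, i, j] <- ts$p_value
      valid[b, i, j] <- is.finite(ts$p_value) && ts$p_value < alpha
    }
  }
  structure(list(slope = slope, p_value = pval, valid = valid,
                 block_centers = blocks$centers, block_bounds = blocks$bounds,
                 layer = layer, lat = anomalies$lat, lon = anomalies$lon,
                 block_years = block_years, alpha = alpha, config = config),
            class = "block_sensitivity")
}

#' Average sensitivity maps across ensemble members
#'
#' Per-product (or per-model) maps are computed first and then averaged cell
#' by cell; a cell's ensemble value uses the members with an estimate there.
#'
#' @param maps list of `sensitivity_map`s on the same grid and layer.
#' @return a `sensitivity_map` whose `slope` and `oob_r2` are member means,
#'   `p_value` the member median, and `n_samples` the member minimum.
#' @export
ensemble_mean <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1L]]
  pile <- function(f, comb) {
    a <- simplify2array(lapply(maps, `[[`, f))
    apply(a, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else comb(v[!is.na(v)]))
  }
  out <- ref
  out$slope <- pile("slope", mean)
  out$oob_r2 <- pile("oob_r2", mean)
  out$p_value <- pile("p_value", median)
  out$n_samples <- pile("n_samples", min)
  out
}
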