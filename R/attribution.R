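#' Per-cell inter-annual trend of growing-season annual means
#'
#' For each cell, averages the variable over growing-season months of every
#' year and takes the Theil-Sen slope of those annual means against year.
#' Cells with fewer than `min_years` annual means are flagged missing.
#'
#' @param field a `grid_field` (raw or anomaly).
#' @param mask logical `(time, lat, lon)` growing-season mask.
#' @param min_years minimum years with a valid annual mean (default 10).
#' @return `(lat, lon)` matrix of trends in units per year.
#' @export
predictor_trends <- function(field, mask, min_years = 10L) {
  v <- field$values
  if (!identical(dim(mask), dim(v))) stop("mask does not match field", call. = FALSE)
  yrs <- year_of(field$time)
  uy <- sort(unique(yrs))
  d <- dim(v)
  out <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    ann <- vapply(uy, function(y) {
      sel <- yrs == y & mask[, i, j] & !is.na(v[, i, j])
      if (!any(sel)) NA_real_ else mean(v[sel, i, j])
    }, numeric(1))
    ok <- is.finite(ann)
    if (sum(ok) < min_years) next
    out[i, j] <- theil_sen(uy[ok], ann[ok])$slope
  }
  out
}

#' Attribute the spatial pattern of sensitivity trends to its controls
#'
#' Fits one random forest of the per-cell sensitivity trend on hydro-climate
#' and ecological predictors across grid cells, computes exact TreeSHAP
#' attributions, and ranks predictors by mean absolute SHAP contribution.
#'
#' @param target `(lat, lon)` matrix of sensitivity trends (typically
#'   `trend_map$sen_slope` over controlled cells).
#' @param predictors named list of `(lat, lon)` matrices (e.g. overall
#'   sensitivity, precipitation trend, soil-moisture trends, temperature /
#'   radiation / VPD trends, non-tree fraction and its trend).
#' @param config an [rf_config()]; the same hyperparameters as the
#'   sensitivity stage.
#' @param min_rows minimum complete cells required (default 50).
#' @return object of class `attribution`: `importance` (data.frame of
#'   predictor and `mean_abs_shap`, descending), `shap` (per-cell SHAP table),
#'   `data` (model table), `oob_r2`, `base`, `cells` (row indices of cells
#'   used).
#' @export
attribute_trends <- function(target, predictors, config = rf_config(),
                             min_rows = 50L) {
  stopifnot(is.list(predictors), length(names(predictors)) == length(predictors))
  tab <- data.frame(target = as.vector(target))
  for (nm in names(predictors)) tab[[nm]] <- as.vector(predictors[[nm]])
  keep <- stats::complete.cases(tab)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) < min_rows)
    stop(sprintf("attribution needs at least %d complete cells, got %d",
                 min_rows, nrow(tab)), call. = FALSE)
  if (sd(tab$target) == 0) stop("degenerate (constant) target", call. = FALSE)
  x <- as.matrix(tab[, names(predictors), drop = FALSE])
  y <- tab$target
  mtry <- max(1L, round(config$max_features_fraction * ncol(x)))
  set.seed(config$random_state)
  rf <- randomForest::randomForest(x, y, ntree = config$n_trees, mtry = mtry,
                                   nodesize = config$nodesize,
                                   keep.forest = TRUE, keep.inbag = TRUE)
  ok <- !is.na(rf$predicted)
  oob_r2 <- 1 - sum((y[ok] - rf$predicted[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
  sv <- shap_values(rf, x)
  imp <- colMeans(abs(sv$phi))
  structure(list(importance = data.frame(predictor = names(sort(imp, decreasing = TRUE)),
                                         mean_abs_shap = unname(sort(imp, decreasing = TRUE))),
                 shap = sv$phi, base = sv$base, data = tab, oob_r2 = oob_r2,
                 cells = which(keep), model = rf),
            class = "attribution")
}

#' Two-way grouping of sensitivity trends by their top two controls
#'
#' Groups cells into a 2-D table over bins of the first control (typically
#' the precipitation trend) and the second (typically overall sensitivity),
#' reporting the median sensitivity trend and the cell count per group.
#'
#' @param trend `(lat, lon)` matrix (or `trend_map`) of sensitivity trends.
#' @param control1,control2 `(lat, lon)` matrices of the two controls.
#' @param bins1,bins2 integer bin counts (quantile bins, default 4) or
#'   numeric break vectors.
#' @return list with `median` and `count` matrices (`bins1` rows x `bins2`
#'   columns) and the break vectors `breaks1`, `breaks2`.
#' @export
group_by_top2 <- function(trend, control1, control2, bins1 = 4L, bins2 = 4L) {
  tr <- if (inherits(trend, "trend_map")) trend$sen_slope else trend
  ok <- !is.na(tr) & !is.na(control1) & !is.na(control2)
  if (!any(ok)) stop("no complete cells to group", call. = FALSE)
  mk_breaks <- function(x, bins) {
    if (length(bins) > 1L) return(sort(bins))
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(br) < 2L) br <- range(x) + c(-0.5, 0.5)
    br
  }
  b1 <- mk_breaks(control1[ok], bins1)
  b2 <- mk_breaks(control2[ok], bins2)
  g1 <- cut(control1[ok], b1, include.lowest = TRUE)
  g2 <- cut(control2[ok], b2, include.lowest = TRUE)
  med <- tapply(tr[ok], list(g1, g2), median)
  cnt <- table(g1, g2)
  list(median = med, count = unclass(cnt), breaks1 = b1, breaks2 = b2)
}
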