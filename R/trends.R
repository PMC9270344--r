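#' Mann-Kendall monotone-trend test with Sen slope
#'
#' Nonparametric trend test: `S = sum_{i<j} sign(y_j - y_i)`, variance with
#' the standard tie correction, Z with continuity correction, two-sided
#' normal p-value; the Sen slope is the median pairwise slope against `t`.
#'
#' @param y numeric series (NAs dropped with their times); at least 4 finite
#'   values required.
#' @param t time positions (default `seq_along(y)`).
#' @return list with `S`, `var_S`, `Z`, `p_value`, `sen_slope`, `n`.
#' @export
mann_kendall <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  o <- order(t)
  y <- y[o]; t <- t[o]
  n <- length(y)
  if (n < 4L) stop("mann_kendall needs at least 4 finite values", call. = FALSE)
  dy <- outer(y, y, "-")
  lower <- lower.tri(dy)
  S <- sum(sign(dy[lower]))  # lower.tri holds y_i - y_j for i > j (later - earlier)
  ties <- table(y)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (var_S == 0) 0 else if (S > 0) (S - 1) / sqrt(var_S)
  else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- if (var_S == 0) 1 else 2 * pnorm(-abs(Z))
  dt <- outer(t, t, "-")[lower]
  dyl <- dy[lower]
  sen <- if (all(dt == 0)) NA_real_ else median((dyl / dt)[dt != 0])
  list(S = S, var_S = var_S, Z = Z, p_value = p, sen_slope = sen, n = n)
}

#' Per-cell trends of block-wise sensitivity
#'
#' Applies the Mann-Kendall test (against block center years) to each cell's
#' valid block sensitivities, restricted to soil-moisture-controlled cells;
#' cells outside the mask are excluded, cells with fewer than `min_blocks`
#' valid blocks are flagged insufficient.
#'
#' @param blocks a `block_sensitivity`.
#' @param sm_controlled logical `(lat, lon)` mask (see [sm_controlled_mask()]).
#' @param alpha per-cell significance level for reporting (default 0.1; the
#'   test itself is two-sided and the full p-value is returned).
#' @param min_blocks minimum valid blocks per cell (default 4).
#' @return object of class `trend_map`: matrices `sen_slope` (sensitivity
#'   change per year), `mk_p`, `n_blocks`, `status`, plus coordinates and
#'   parameters.
#' @export
trend_map <- function(blocks, sm_controlled, alpha = 0.1, min_blocks = 4L) {
  d <- dim(blocks$slope)
  sen <- matrix(NA_real_, d[2], d[3])
  mkp <- matrix(NA_real_, d[2], d[3])
  nb <- matrix(0L, d[2], d[3])
  status <- matrix("excluded", d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    if (!isTRUE(sm_controlled[i, j])) next
    v <- blocks$valid[, i, j]
    nb[i, j] <- sum(v)
    if (sum(v) < min_blocks) { status[i, j] <- "insufficient"; next }
    mk <- mann_kendall(blocks$slope[v, i, j], blocks$block_centers[v])
    sen[i, j] <- mk$sen_slope
    mkp[i, j] <- mk$p_value
    status[i, j] <- "ok"
  }
  structure(list(sen_slope = sen, mk_p = mkp, n_blocks = nb, status = status,
                 lat = blocks$lat, lon = blocks$lon, alpha = alpha,
                 block_years = blocks$block_years),
            class = "trend_map")
}

# area-weighted median (type-1 weighted quantile at 0.5)
weighted_median <- function(x, w) {
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Global series of area-aggregated block sensitivity
#'
#' Per block, the area-weighted aggregate (median by default) of valid block
#' sensitivities over soil-moisture-controlled cells, re-based so the first
#' block is zero ("change since the first block"), with a Mann-Kendall test
#' of the aggregate series.
#'
#' @param blocks a `block_sensitivity`.
#' @param sm_controlled logical `(lat, lon)` mask.
#' @param weights `(lat, lon)` area weights; default cosine-latitude.
#' @param stat `"median"` (default) or `"mean"`.
#' @param alpha significance level for the global test (default 0.01).
#' @return object of class `global_series`: `block_centers`, `values`
#'   (re-based aggregate), `raw` (un-based aggregate), `mk` (Mann-Kendall
#'   result), `significant`.
#' @export
global_series <- function(blocks, sm_controlled,
                          weights = area_weights(blocks$lat, blocks$lon),
                          stat = c("median", "mean"), alpha = 0.01) {
  stat <- match.arg(stat)
  if (!any(sm_controlled)) stop("empty soil-moisture-controlled mask", call. = FALSE)
  nb <- dim(blocks$slope)[1L]
  agg <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    s <- blocks$slope[b, , ]
    v <- blocks$valid[b, , ] & sm_controlled
    if (!any(v)) next
    agg[b] <- if (stat == "median") weighted_median(s[v], weights[v])
    else sum(s[v] * weights[v]) / sum(weights[v])
  }
  base <- agg[which(is.finite(agg))[1L]]
  mk <- mann_kendall(agg, blocks$block_centers)
  structure(list(block_centers = blocks$block_centers, values = agg - base,
                 raw = agg, stat = stat, mk = mk, alpha = alpha,
                 significant = is.finite(mk$p_value) && mk$p_value < alpha),
            class = "global_series")
}

#' Area fractions of increasing and decreasing sensitivity trends
#'
#' Cosine-latitude-weighted fractions of the study area with positive /
#' negative Sen slope, and the significant (p < alpha) subsets. The
#' denominator is the whole study-area weight, so cells excluded from the
#' trend analysis count toward neither sign and the increasing / decreasing /
#' remaining partition sums to 1.
#'
#' @param trend a `trend_map`.
#' @param study_area logical `(lat, lon)` denominator mask; default = all
#'   cells with any status.
#' @param weights area weights (default cosine-latitude).
#' @param alpha significance level (default 0.1).
#' @return list of fractions: `increasing`, `decreasing`,
#'   `significant_increasing`, `significant_decreasing`, `remaining`.
#' @export
area_fractions <- function(trend, study_area = NULL,
                           weights = area_weights(trend$lat, trend$lon),
                           alpha = 0.1) {
  if (is.null(study_area)) study_area <- matrix(TRUE, nrow(trend$sen_slope),
                                                ncol(trend$sen_slope))
  wtot <- sum(weights[study_area])
  s <- trend$sen_slope; p <- trend$mk_p
  frac <- function(cond) {
    cond[is.na(cond)] <- FALSE
    sum(weights[cond & study_area]) / wtot
  }
  inc <- frac(s > 0); dec <- frac(s < 0)
  list(increasing = inc, decreasing = dec,
       significant_increasing = frac(s > 0 & p < alpha),
       significant_decreasing = frac(s < 0 & p < alpha),
       remaining = 1 - inc - dec)
}

#' Response function of sensitivity against mean soil moisture
#'
#' Bins significantly sensitive cells (p < `p_threshold`) by their
#' growing-season mean soil moisture and summarizes the sensitivity
#' distribution per bin (median and interquartile range), together with the
#' marginal soil-moisture histogram.
#'
#' @param sens a `sensitivity_map`.
#' @param mean_sm `(lat, lon)` growing-season mean soil moisture (mm).
#' @param bins number of equal-width bins (default 10) or a numeric vector of
#'   break points.
#' @param p_threshold significance filter (default 0.01).
#' @return data.frame with one row per bin: `mid`, `lo`, `hi`, `n`,
#'   `median`, `q25`, `q75` (NA for empty bins).
#' @export
response_function <- function(sens, mean_sm, bins = 10L, p_threshold = 0.01) {
  ok <- !is.na(sens$slope) & !is.na(sens$p_value) & sens$p_value < p_threshold &
    !is.na(mean_sm)
  x <- mean_sm[ok]; y <- sens$slope[ok]
  if (!length(x)) stop("no significant cells to bin", call. = FALSE)
  breaks <- if (length(bins) == 1L)
    seq(min(x), max(x), length.out = bins + 1L) else sort(bins)
  grp <- cut(x, breaks, include.lowest = TRUE)
  agg <- function(f) as.numeric(tapply(y, grp, f))
  data.frame(mid = (head(breaks, -1) + breaks[-1]) / 2,
             lo = head(breaks, -1), hi = breaks[-1],
             n = as.integer(table(grp)),
             median = agg(median),
             q25 = agg(function(v) quantile(v, 0.25)),
             q75 = agg(function(v) quantile(v, 0.75)))
}

#' Compare two sensitivity maps across climate regimes
#'
#' Per climate regime: mean difference `a - b` over shared valid cells and
#' the Pearson correlation of the two maps across those cells. Regimes with
#' fewer than 3 shared cells are flagged.
#'
#' @param map_a,map_b `sensitivity_map`s (or plain matrices) on one grid.
#' @param regimes result of [climate_regime_bins()].
#' @return data.frame with one row per non-empty regime: `regime`, `n`,
#'   `mean_diff`, `correlation`, `flagged`.
#' @export
regime_compare <- function(map_a, map_b, regimes) {
  a <- if (inherits(map_a, "sensitivity_map")) map_a$slope else map_a
  b <- if (inherits(map_b, "sensitivity_map")) map_b$slope else map_b
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(regimes$labels)))
    stop("maps and regime labels are not co-registered", call. = FALSE)
  shared <- !is.na(a) & !is.na(b) & !is.na(regimes$labels)
  regs <- sort(unique(regimes$labels[shared]))
  out <- lapply(regs, function(r) {
    sel <- shared & regimes$labels == r
    n <- sum(sel)
    data.frame(regime = r, n = n,
               mean_diff = mean(a[sel] - b[sel]),
               correlation = if (n >= 3 && sd(a[sel]) > 0 && sd(b[sel]) > 0)
                 cor(a[sel], b[sel]) else NA_real_,
               flagged = n < 3)
  })
  do.call(rbind, out)
}
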