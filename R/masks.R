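#' Study-area mask from vegetation cover and irrigation fractions
#'
#' A cell belongs to the study area iff total vegetation cover (tree +
#' non-tree) is at least 5% and the irrigated fraction is at most 10%
#' (inclusive bounds).
#'
#' @param tree_cover,nontree_cover,irrigation_fraction `(lat, lon)` matrices of
#'   fractions in [0, 1] (or percent in [0, 100], auto-detected when any value
#'   exceeds 1 and declared consistently).
#' @param cover_min,irrigation_max thresholds as fractions.
#' @return logical `(lat, lon)` matrix.
#' @export
study_area_mask <- function(tree_cover, nontree_cover, irrigation_fraction,
                            cover_min = 0.05, irrigation_max = 0.10) {
  norm <- function(x, nm) {
    if (any(x < 0, na.rm = TRUE)) stop(nm, " has negative fractions", call. = FALSE)
    if (any(x > 1, na.rm = TRUE)) {
      if (any(x > 100, na.rm = TRUE))
        stop(nm, " outside [0, 1] or [0, 100]", call. = FALSE)
      x <- x / 100
    }
    x
  }
  tc <- norm(tree_cover, "tree_cover")
  nc <- norm(nontree_cover, "nontree_cover")
  ir <- norm(irrigation_fraction, "irrigation_fraction")
  (tc + nc) >= cover_min & ir <= irrigation_max & !is.na(tc + nc + ir)
}

#' Aridity index from long-term mean net radiation and precipitation
#'
#' The ratio of long-term mean net radiation to energy-equivalent
#' precipitation, where precipitation (a water flux) is converted to an energy
#' flux through the latent heat of vaporization (2.45 MJ/kg). Values above 1
#' denote dry (semi-arid) regimes. Radiation in W/m2 is converted to
#' MJ/m2/day (x 0.0864); precipitation in mm/month to mm/day (/ 30.44,
#' i.e. kg/m2/day).
#'
#' @param net_radiation `grid_field` (W m-2) or a precomputed `(lat, lon)`
#'   long-term mean matrix in MJ m-2 day-1.
#' @param precipitation `grid_field` (mm/month) or a `(lat, lon)` long-term
#'   mean matrix in mm/day.
#' @param lambda latent heat of vaporization, MJ per kg (= per mm m-2).
#' @return `(lat, lon)` matrix; `Inf` (maximally arid) where mean
#'   precipitation is zero and radiation positive.
#' @export
aridity_index <- function(net_radiation, precipitation, lambda = 2.45) {
  rn <- if (inherits(net_radiation, "grid_field"))
    apply(net_radiation$values, c(2, 3), mean, na.rm = TRUE) * 0.0864
  else net_radiation
  pr <- if (inherits(precipitation, "grid_field"))
    apply(precipitation$values, c(2, 3), mean, na.rm = TRUE) / 30.44
  else precipitation
  ai <- rn / (lambda * pr)
  ai[pr == 0 & rn > 0] <- Inf
  ai[pr == 0 & rn <= 0] <- NA_real_
  ai
}

#' Soil-moisture-controlled region mask
#'
#' Cells with significantly positive overall sensitivity (slope > 0 and
#' p < alpha). Cells with negative or non-significant (p >= alpha) slopes —
#' and cells with no estimate — are non-soil-moisture-controlled.
#'
#' @param sensitivity_map a [sensitivity_map] (from [overall_sensitivity()]).
#' @param alpha significance level (default 0.1).
#' @return logical `(lat, lon)` matrix.
#' @export
sm_controlled_mask <- function(sensitivity_map, alpha = 0.1) {
  s <- sensitivity_map$slope; p <- sensitivity_map$p_value
  ok <- !is.na(s) & !is.na(p) & s > 0 & p < alpha
  ok
}

#' Climate-regime bins over (aridity, mean temperature)
#'
#' Two-dimensional binning of study-area cells by aridity index and long-term
#' mean temperature; used to compare sensitivity maps across climate regimes.
#'
#' @param aridity,mean_temp `(lat, lon)` matrices.
#' @param aridity_edges interior bin edges on the aridity axis (default
#'   `c(0.5, 1, 2)`).
#' @param temp_edges interior edges on the temperature axis; default = the
#'   quartiles of `mean_temp` over the study area.
#' @param study_area optional logical matrix restricting the labeling.
#' @return list with `labels` (integer `(lat, lon)` matrix, `NA` outside the
#'   study area), `aridity_bin`, `temp_bin`, `n_regimes`, and the edge vectors.
#' @export
climate_regime_bins <- function(aridity, mean_temp,
                                aridity_edges = c(0.5, 1, 2),
                                temp_edges = NULL, study_area = NULL) {
  if (is.null(study_area)) study_area <- !is.na(aridity) & !is.na(mean_temp)
  if (!any(study_area)) stop("empty study area", call. = FALSE)
  if (is.null(temp_edges))
    temp_edges <- unname(quantile(mean_temp[study_area], c(0.25, 0.5, 0.75),
                                  na.rm = TRUE))
  abr <- c(-Inf, sort(aridity_edges), Inf)
  tbr <- c(-Inf, sort(unique(temp_edges)), Inf)
  ab <- matrix(findInterval(aridity, abr[-1], left.open = TRUE) + 1L,
               nrow(aridity))
  tb <- matrix(findInterval(mean_temp, tbr[-1], left.open = TRUE) + 1L,
               nrow(mean_temp))
  na_t <- length(abr) - 1L
  lab <- (tb - 1L) * na_t + ab
  lab[!study_area] <- NA_integer_
  ab[!study_area] <- NA_integer_; tb[!study_area] <- NA_integer_
  list(labels = lab, aridity_bin = ab, temp_bin = tb,
       n_regimes = na_t * (length(tbr) - 1L),
       aridity_edges = sort(aridity_edges), temp_edges = sort(unique(temp_edges)))
}

#' Area weights proportional to grid-cell area
#'
#' Cosine-latitude weights, the standard approximation of actual cell areas on
#' a regular lat-lon grid.
#'
#' @param lat,lon coordinate vectors (degrees).
#' @return `(lat, lon)` matrix of weights (not normalized).
#' @export
area_weights <- function(lat, lon) {
  matrix(cos(lat * pi / 180), length(lat), length(lon))
}
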