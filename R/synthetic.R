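#' Configuration of the synthetic gridded dataset
#'
#' Defines the study conditions the generator emulates: an 0.5-degree grid of
#' monthly series (1982-2017 by default) for LAI, three volumetric
#' soil-moisture layers (0-7, 7-28, 28-100 cm), air temperature, precipitation,
#' vapor pressure deficit and solar radiation. Each variable is a monthly
#' climatology plus a linear long-term drift plus an AR(1) anomaly; the LAI
#' anomaly carries an imposed linear response to the sub- and near-surface
#' soil-moisture water-depth anomalies (mm) and to the temperature anomaly,
#' with optional linear drift of the sub-surface response over time.
#'
#' @param n_lat,n_lon grid size (cells).
#' @param start_year,end_year calendar years covered (inclusive).
#' @param base_sensitivity_sub imposed LAI sensitivity to sub-surface soil
#'   moisture, LAI anomaly per mm; scalar or `(n_lat, n_lon)` matrix.
#' @param sensitivity_trend_sub linear drift of that sensitivity per year;
#'   scalar or matrix.
#' @param base_sensitivity_near imposed sensitivity to near-surface soil
#'   moisture (per mm); scalar or matrix.
#' @param temp_effect slope of LAI anomaly on temperature anomaly (per degC).
#' @param noise_sd standard deviation of the LAI anomaly noise (>= 0).
#' @param sm_autocorr lag-1 autocorrelation of all AR(1) anomalies, in [0, 1).
#' @param anomaly_sd named stationary standard deviations of the AR(1)
#'   anomalies: `smnear`/`smsub` in mm of water depth, others in native units.
#' @param climatology_means,seasonal_amplitudes named per-variable annual mean
#'   and seasonal (cosine, July peak) amplitude.
#' @param longterm_trends named per-variable linear drift per year.
#' @param temp_lat_gradient degC change in mean temperature per latitude row.
#' @param precip_lon_gradient mm/month change in mean precipitation per
#'   longitude column (creates an aridity gradient).
#' @param lat0,lon0 coordinates of the first grid cell (degrees).
#' @param tree_cover,nontree_cover,irrigation_fraction static cover fractions
#'   in [0, 1]; scalars or matrices.
#' @param seed integer seed making generation deterministic.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_lat = 8L, n_lon = 8L,
                         start_year = 1982L, end_year = 2017L,
                         base_sensitivity_sub = 0.5,
                         sensitivity_trend_sub = 0,
                         base_sensitivity_near = 0.2,
                         temp_effect = 0.05,
                         noise_sd = 0.2,
                         sm_autocorr = 0.5,
                         anomaly_sd = c(smnear = 0.6, smsub = 1.0, temp = 1.0,
                                        precip = 10, vpd = 1.5, rad = 2.0),
                         climatology_means = c(lai = 2.0, smnear_vol = 0.25,
                                               smsub_vol = 0.28, temp = 2,
                                               precip = 60, vpd = 8, rad = 180),
                         seasonal_amplitudes = c(lai = 1.0, smnear_vol = 0.03,
                                                 smsub_vol = 0.02, temp = 14,
                                                 precip = 25, vpd = 3, rad = 80),
                         longterm_trends = c(lai = 0.004, smnear_vol = -2e-4,
                                             smsub_vol = -2e-4, temp = 0.03,
                                             precip = -0.2, vpd = 0.02, rad = 0.1),
                         temp_lat_gradient = -0.4,
                         precip_lon_gradient = -3,
                         lat0 = 48.25, lon0 = 10.25,
                         tree_cover = 0.3, nontree_cover = 0.4,
                         irrigation_fraction = 0,
                         seed = 42L) {
  cfg <- list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
              start_year = as.integer(start_year), end_year = as.integer(end_year),
              base_sensitivity_sub = base_sensitivity_sub,
              sensitivity_trend_sub = sensitivity_trend_sub,
              base_sensitivity_near = base_sensitivity_near,
              temp_effect = temp_effect, noise_sd = noise_sd,
              sm_autocorr = sm_autocorr, anomaly_sd = anomaly_sd,
              climatology_means = climatology_means,
              seasonal_amplitudes = seasonal_amplitudes,
              longterm_trends = longterm_trends,
              temp_lat_gradient = temp_lat_gradient,
              precip_lon_gradient = precip_lon_gradient,
              lat0 = lat0, lon0 = lon0,
              tree_cover = tree_cover, nontree_cover = nontree_cover,
              irrigation_fraction = irrigation_fraction,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_lat < 1L || cfg$n_lon < 1L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (cfg$end_year <= cfg$start_year)
    stop("end_year must exceed start_year", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$sm_autocorr < 0 || cfg$sm_autocorr >= 1)
    stop("sm_autocorr must lie in [0, 1)", call. = FALSE)
  for (nm in c("base_sensitivity_sub", "sensitivity_trend_sub",
               "base_sensitivity_near", "tree_cover", "nontree_cover",
               "irrigation_fraction")) {
    v <- cfg[[nm]]
    if (is.matrix(v) && !identical(dim(v), c(cfg$n_lat, cfg$n_lon)))
      stop(sprintf("`%s` matrix must be (n_lat, n_lon)", nm), call. = FALSE)
    if (!is.matrix(v) && length(v) != 1L)
      stop(sprintf("`%s` must be scalar or (n_lat, n_lon) matrix", nm), call. = FALSE)
  }
  invisible(cfg)
}

as_cell_matrix <- function(v, n_lat, n_lon) {
  if (is.matrix(v)) v else matrix(v, n_lat, n_lon)
}

# depths (m) of the three emitted volumetric soil layers, ERA5-Land style
soil_layer_depths <- function() list(c(0, 0.07), c(0.07, 0.28), c(0.28, 1.00))

#' Generate a synthetic gridded dataset with known ground truth
#'
#' Builds monthly `grid_field`s for LAI, three volumetric soil-moisture layers,
#' temperature, precipitation, VPD and radiation, plus static cover fields and
#' a `synth_truth` object holding the imposed sensitivity fields, their drift,
#' the soil-moisture-controlled mask and the noise-free anomaly components used
#' by parameter-recovery tests. Soil moisture is emitted in m3/m3 per layer so
#' the preprocessing depth-weighted conversion to mm is exercised.
#'
#' @param config a [synth_config()].
#' @return list with elements `fields` (named `grid_field`s; `sm_layers` is a
#'   list of three layers with a `depths` attribute), `static` (cover
#'   matrices), `truth` (`synth_truth`), and `config`.
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  nlat <- config$n_lat; nlon <- config$n_lon
  time <- month_seq(config$start_year, config$end_year)
  nt <- length(time)
  lat <- config$lat0 + 0.5 * (seq_len(nlat) - 1L)
  lon <- config$lon0 + 0.5 * (seq_len(nlon) - 1L)
  mon <- month_of(time)
  yr_frac <- decimal_year(time) - config$start_year
  seas <- cos(2 * pi * (mon - 7) / 12)  # July peak

  rho <- config$sm_autocorr
  ar1 <- function(sd) {
    # stationary AR(1), per cell independent
    e <- array(rnorm(nt * nlat * nlon), c(nt, nlat, nlon))
    x <- array(0, c(nt, nlat, nlon))
    x[1L, , ] <- e[1L, , ] * sd
    f <- sd * sqrt(1 - rho^2)
    for (t in seq_len(nt)[-1L]) x[t, , ] <- rho * x[t - 1L, , ] + f * e[t, , ]
    x
  }
  clim <- function(var, mean_field = NULL) {
    m <- if (is.null(mean_field)) config$climatology_means[[var]] else mean_field
    base <- array(rep(m, each = nt), c(nt, nlat, nlon))  # works for scalar or matrix
    if (is.matrix(m)) base <- aperm(array(m, c(nlat, nlon, nt)), c(3, 1, 2))
    base + config$seasonal_amplitudes[[var]] * seas +
      config$longterm_trends[[var]] * yr_frac
  }

  sdv <- config$anomaly_sd
  a_near <- ar1(sdv[["smnear"]])   # mm water depth
  a_sub  <- ar1(sdv[["smsub"]])    # mm water depth
  a_temp <- ar1(sdv[["temp"]])
  a_prec <- ar1(sdv[["precip"]])
  a_vpd  <- ar1(sdv[["vpd"]])
  a_rad  <- ar1(sdv[["rad"]])
  eps    <- if (config$noise_sd > 0)
    array(rnorm(nt * nlat * nlon, sd = config$noise_sd), c(nt, nlat, nlon))
  else array(0, c(nt, nlat, nlon))

  depths <- soil_layer_depths()
  th_mm <- vapply(depths, function(d) 1000 * (d[2] - d[1]), numeric(1))  # 70,210,720
  tmean <- matrix(config$climatology_means[["temp"]], nlat, nlon) +
    config$temp_lat_gradient * (row(matrix(0, nlat, nlon)) - 1L)
  pmean <- matrix(config$climatology_means[["precip"]], nlat, nlon) +
    config$precip_lon_gradient * (col(matrix(0, nlat, nlon)) - 1L)

  b_sub0 <- as_cell_matrix(config$base_sensitivity_sub, nlat, nlon)
  drift  <- as_cell_matrix(config$sensitivity_trend_sub, nlat, nlon)
  b_near <- as_cell_matrix(config$base_sensitivity_near, nlat, nlon)
  bt <- array(NA_real_, c(nt, nlat, nlon))  # time-varying sub sensitivity
  for (t in seq_len(nt)) bt[t, , ] <- b_sub0 + drift * yr_frac[t]
  expand2 <- function(m) aperm(array(m, c(nlat, nlon, nt)), c(3, 1, 2))
  lai_signal <- bt * a_sub + expand2(b_near) * a_near + config$temp_effect * a_temp

  # volumetric layers: layer 1 carries the near anomaly, layers 2+3 split the
  # sub anomaly proportional to thickness so depth-weighting reconstructs it
  v1 <- clim("smnear_vol") + a_near / th_mm[1]
  sub_clim <- clim("smsub_vol")
  v2 <- sub_clim + (a_sub * th_mm[2] / (th_mm[2] + th_mm[3])) / th_mm[2]
  v3 <- sub_clim + (a_sub * th_mm[3] / (th_mm[2] + th_mm[3])) / th_mm[3]

  gf <- function(vals, units, name) grid_field(vals, units, time, lat, lon, name)
  fields <- list(
    lai    = gf(pmax(clim("lai") + lai_signal + eps, 0), "m2/m2", "lai"),
    sm_layers = structure(list(gf(v1, "m3/m3", "sm_layer1"),
                               gf(v2, "m3/m3", "sm_layer2"),
                               gf(v3, "m3/m3", "sm_layer3")),
                          depths = depths),
    temp   = gf(clim("temp", tmean) + a_temp, "degC", "temp"),
    precip = gf(pmax(clim("precip", pmean) + a_prec, 0), "mm/month", "precip"),
    vpd    = gf(pmax(clim("vpd") + a_vpd, 0), "hPa", "vpd"),
    rad    = gf(pmax(clim("rad") + a_rad, 0), "W m-2", "rad"))

  mid <- mean(yr_frac)
  truth <- structure(list(
    true_overall_sensitivity = b_sub0 + drift * mid,
    true_sensitivity_trend_per_year = drift,
    true_sensitivity_near = b_near,
    controlled_mask = (b_sub0 + drift * mid) > 0,
    components = list(smnear_anom_mm = a_near, smsub_anom_mm = a_sub,
                      temp_anom = a_temp, lai_signal = lai_signal),
    lat = lat, lon = lon, time = time), class = "synth_truth")

  list(fields = fields,
       static = list(tree_cover = as_cell_matrix(config$tree_cover, nlat, nlon),
                     nontree_cover = as_cell_matrix(config$nontree_cover, nlat, nlon),
                     irrigation_fraction = as_cell_matrix(config$irrigation_fraction,
                                                          nlat, nlon)),
       truth = truth, config = config)
}
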