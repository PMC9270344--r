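nc_missval <- 9.96921e36

#' Write gridded fields to a CF-style NetCDF file
#'
#' Stores one or more `grid_field`s sharing a grid into a single file with
#' `lon`, `lat`, `time` dimensions (time in days since 1970-01-01) and a
#' units attribute per variable.
#'
#' @param fields named list of `grid_field`s (or a single field).
#' @param path output file path (.nc).
#' @param global_attrs optional named list of global attributes.
#' @return `path`, invisibly.
#' @export
write_grid <- function(fields, path, global_attrs = list()) {
  if (inherits(fields, "grid_field")) fields <- stats::setNames(list(fields),
                                                                fields$name)
  ref <- fields[[1L]]
  do.call(stopifnot_same_grid, fields)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", ref$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", ref$lat)
  dtime <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.numeric(ref$time), unlim = TRUE)
  vars <- lapply(names(fields), function(nm)
    ncdf4::ncvar_def(nm, fields[[nm]]$units, list(dlon, dlat, dtime),
                     missval = nc_missval, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(fields)) {
    # internal layout is (time, lat, lon); NetCDF wants (lon, lat, time)
    ncdf4::ncvar_put(nc, vars[[k]], aperm(fields[[k]]$values, c(3, 2, 1)))
  }
  for (nm in names(global_attrs))
    ncdf4::ncatt_put(nc, 0, nm, global_attrs[[nm]])
  invisible(path)
}

#' Read one gridded variable from a CF-style NetCDF file
#'
#' Requires `lon`, `lat` and `time` dimensions; units and missing values are
#' preserved. Cover-type variables declared in percent units (`"%"` or
#' `"percent"`) are normalized to fractions.
#'
#' @param path NetCDF file.
#' @param variable variable name.
#' @return a `grid_field`.
#' @export
read_grid <- function(path, variable) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop(sprintf("variable '%s' not found in %s", variable, path), call. = FALSE)
  v <- nc$var[[variable]]
  dn <- vapply(v$dim, `[[`, character(1), "name")
  for (need in c("lon", "lat", "time"))
    if (!need %in% dn)
      stop(sprintf("variable '%s' lacks a '%s' dimension", variable, need),
           call. = FALSE)
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  dim(vals) <- vapply(v$dim, `[[`, numeric(1), "len")
  vals <- aperm(vals, match(c("time", "lat", "lon"), dn))
  tdim <- v$dim[[which(dn == "time")]]
  if (!grepl("days since 1970-01-01", tdim$units))
    stop("unsupported time units: ", tdim$units, call. = FALSE)
  units <- v$units
  if (units %in% c("%", "percent")) {
    vals <- vals / 100
    units <- "fraction"
  }
  grid_field(vals, units,
             time = as.Date(as.vector(tdim$vals), origin = "1970-01-01"),
             lat = v$dim[[which(dn == "lat")]]$vals,
             lon = v$dim[[which(dn == "lon")]]$vals, name = variable)
}

write_static_nc <- function(mats, lat, lon, path, units = "fraction") {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  vars <- lapply(names(mats), function(nm)
    ncdf4::ncvar_def(nm, units, list(dlon, dlat), missval = nc_missval,
                     prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(mats)) ncdf4::ncvar_put(nc, vars[[k]], t(mats[[k]]))
  invisible(path)
}

read_static_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  out <- lapply(names(nc$var), function(nm) t(ncdf4::ncvar_get(nc, nm)))
  stats::setNames(out, names(nc$var))
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Creates a directory holding `fields.nc` (LAI, the three volumetric
#' soil-moisture layers, temperature, precipitation, VPD, radiation),
#' `static.nc` (cover fractions) and `truth.json` (imposed sensitivity
#' fields, drift, controlled mask). Round-trips through [read_fixture()].
#'
#' @param dataset result of [generate_dataset()].
#' @param path target directory.
#' @param overwrite overwrite an existing directory (default FALSE; an
#'   existing directory without this flag is an error).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, path, overwrite = FALSE) {
  if (dir.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; use overwrite = TRUE", path), call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- dataset$fields
  depths <- attr(f$sm_layers, "depths")
  all_fields <- c(list(lai = f$lai, sm_layer1 = f$sm_layers[[1]],
                       sm_layer2 = f$sm_layers[[2]], sm_layer3 = f$sm_layers[[3]],
                       temp = f$temp, precip = f$precip, vpd = f$vpd,
                       rad = f$rad))
  write_grid(all_fields, file.path(path, "fields.nc"),
             global_attrs = list(layer_tops_m = vapply(depths, `[`, numeric(1), 1),
                                 layer_bottoms_m = vapply(depths, `[`, numeric(1), 2)))
  write_static_nc(dataset$static, f$lai$lat, f$lai$lon,
                  file.path(path, "static.nc"))
  tr <- dataset$truth
  sidecar <- list(true_overall_sensitivity = tr$true_overall_sensitivity,
                  true_sensitivity_trend_per_year = tr$true_sensitivity_trend_per_year,
                  true_sensitivity_near = tr$true_sensitivity_near,
                  controlled_mask = tr$controlled_mask,
                  lat = tr$lat, lon = tr$lon)
  writeLines(jsonlite::toJSON(sidecar, digits = NA, matrix = "rowmajor"),
             file.path(path, "truth.json"))
  invisible(path)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param path fixture directory.
#' @return list with `fields` (as in [generate_dataset()]), `static`, and
#'   `truth` (sidecar fields; no noise-free components).
#' @export
read_fixture <- function(path) {
  fp <- file.path(path, "fields.nc")
  nms <- c("lai", "sm_layer1", "sm_layer2", "sm_layer3", "temp", "precip",
           "vpd", "rad")
  fields <- stats::setNames(lapply(nms, read_grid, path = fp), nms)
  nc <- ncdf4::nc_open(fp)
  tops <- ncdf4::ncatt_get(nc, 0, "layer_tops_m")$value
  bots <- ncdf4::ncatt_get(nc, 0, "layer_bottoms_m")$value
  ncdf4::nc_close(nc)
  sm <- structure(fields[c("sm_layer1", "sm_layer2", "sm_layer3")],
                  depths = Map(c, tops, bots), names = NULL)
  tr <- jsonlite::fromJSON(file.path(path, "truth.json"))
  tr$controlled_mask <- matrix(as.logical(tr$controlled_mask),
                               nrow(tr$true_overall_sensitivity))
  list(fields = list(lai = fields$lai, sm_layers = sm, temp = fields$temp,
                     precip = fields$precip, vpd = fields$vpd,
                     rad = fields$rad),
       static = read_static_nc(file.path(path, "static.nc")),
       truth = structure(tr, class = "synth_truth"))
}
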