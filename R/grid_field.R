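#' Gridded monthly field
#'
#' The common currency of the pipeline: a `(time, lat, lon)` array of monthly
#' values with units and a monthly calendar. Missing data are `NA`.
#'
#' @param values numeric array with dimensions `(time, lat, lon)`.
#' @param units unit string (non-empty), e.g. `"m3/m3"`, `"mm"`, `"degC"`.
#' @param time `Date` vector of month starts, strictly increasing, monthly
#'   spacing, length `dim(values)[1]`.
#' @param lat,lon monotone coordinate vectors (degrees) matching the trailing
#'   dimensions of `values`.
#' @param name optional variable name.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(values, units, time, lat, lon, name = "field") {
  if (length(dim(values)) != 3L)
    stop("`values` must be a (time, lat, lon) array", call. = FALSE)
  if (!nzchar(units)) stop("`units` must be non-empty", call. = FALSE)
  d <- dim(values)
  if (length(time) != d[1L]) stop("time length does not match values", call. = FALSE)
  if (length(lat) != d[2L] || length(lon) != d[3L])
    stop("lat/lon lengths do not match values", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  mdiff <- diff(12L * as.integer(format(time, "%Y")) + as.integer(format(time, "%m")))
  if (length(mdiff) && any(mdiff != 1L))
    stop("time must have monthly spacing", call. = FALSE)
  if (is.unsorted(lat) && is.unsorted(rev(lat)))
    stop("lat must be monotone", call. = FALSE)
  if (is.unsorted(lon) && is.unsorted(rev(lon)))
    stop("lon must be monotone", call. = FALSE)
  structure(list(values = values, units = units, time = as.Date(time),
                 lat = as.numeric(lat), lon = as.numeric(lon), name = name),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_field> %s [%s]  %d months x %d lat x %d lon\n",
              x$name, x$units, d[1L], d[2L], d[3L]))
  cat(sprintf("  %s .. %s | %.1f%% missing\n", format(x$time[1L]),
              format(x$time[length(x$time)]),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

# months (1..12) and fractional decimal years of a monthly calendar
month_of <- function(time) as.integer(format(time, "%m"))
year_of  <- function(time) as.integer(format(time, "%Y"))
decimal_year <- function(time) year_of(time) + (month_of(time) - 0.5) / 12

# monthly Date sequence covering calendar years start..end
month_seq <- function(start_year, end_year) {
  seq(as.Date(sprintf("%d-01-01", start_year)),
      as.Date(sprintf("%d-12-01", end_year)), by = "month")
}

stopifnot_same_grid <- function(...) {
  fl <- list(...)
  ref <- fl[[1L]]
  for (f in fl[-1L]) {
    if (!identical(dim(f$values), dim(ref$values)) ||
        !isTRUE(all.equal(f$lat, ref$lat)) || !isTRUE(all.equal(f$lon, ref$lon)) ||
        !identical(f$time, ref$time))
      stop("fields are not co-registered (grid/calendar mismatch)", call. = FALSE)
  }
  invisible(TRUE)
}
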