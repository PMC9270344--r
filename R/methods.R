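#' @export
print.sensitivity_map <- function(x, ...) {
  n_ok <- sum(x$status == "ok")
  cat(sprintf("<sensitivity_map> dLAI/dSM%s on %d x %d grid\n", x$layer,
              length(x$lat), length(x$lon)))
  cat(sprintf("  ok %d | gated %d | insufficient %d | missing %d\n",
              n_ok, sum(x$status == "gated"), sum(x$status == "insufficient"),
              sum(x$status == "missing")))
  if (n_ok) cat(sprintf("  slope median %.4g [IQR %.4g, %.4g] LAI anomaly per mm\n",
                        median(x$slope, na.rm = TRUE),
                        quantile(x$slope, 0.25, na.rm = TRUE),
                        quantile(x$slope, 0.75, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.sensitivity_map <- function(object, alpha = 0.01, ...) {
  ok <- !is.na(object$slope)
  out <- list(layer = object$layer, n_cells = length(object$slope),
              n_estimated = sum(ok),
              n_significant = sum(ok & object$p_value < alpha),
              n_significant_positive = sum(ok & object$p_value < alpha &
                                             object$slope > 0),
              median_slope = median(object$slope, na.rm = TRUE),
              median_oob_r2 = median(object$oob_r2, na.rm = TRUE),
              alpha = alpha)
  class(out) <- "summary.sensitivity_map"
  out
}

#' @export
print.summary.sensitivity_map <- function(x, ...) {
  cat(sprintf("Overall LAI sensitivity to %s-surface soil moisture\n", x$layer))
  cat(sprintf("  cells estimated: %d of %d\n", x$n_estimated, x$n_cells))
  cat(sprintf("  significant (p < %g): %d (%d positive)\n", x$alpha,
              x$n_significant, x$n_significant_positive))
  cat(sprintf("  median slope: %.4g LAI anomaly per mm | median OOB R2: %.3f\n",
              x$median_slope, x$median_oob_r2))
  invisible(x)
}

#' @export
coef.sensitivity_map <- function(object, ...) object$slope

#' @export
plot.sensitivity_map <- function(x, ...) {
  z <- t(x$slope)  # image() wants x = first dim
  graphics::image(x$lon, x$lat, z, xlab = "lon", ylab = "lat",
                  main = sprintf("dLAI/dSM%s (Theil-Sen of SHAP dependence)",
                                 x$layer),
                  col = grDevices::hcl.colors(21, "RdYlBu", rev = TRUE), ...)
  invisible(x)
}

#' @export
print.block_sensitivity <- function(x, ...) {
  nb <- dim(x$slope)[1L]
  cat(sprintf("<block_sensitivity> %d blocks of %d years (%d-%d .. %d-%d), layer %s\n",
              nb, x$block_years, x$block_bounds$first[1], x$block_bounds$last[1],
              x$block_bounds$first[nb], x$block_bounds$last[nb], x$layer))
  cat(sprintf("  valid estimates: %d of %d cell-blocks\n", sum(x$valid),
              length(x$valid)))
  invisible(x)
}

#' @export
print.trend_map <- function(x, ...) {
  ok <- x$status == "ok"
  cat(sprintf("<trend_map> Sen slope of %d-year-block sensitivity\n", x$block_years))
  cat(sprintf("  cells: ok %d | insufficient %d | excluded %d\n", sum(ok),
              sum(x$status == "insufficient"), sum(x$status == "excluded")))
  if (any(ok))
    cat(sprintf("  increasing %d | decreasing %d | significant (p < %g) %d\n",
                sum(x$sen_slope > 0, na.rm = TRUE),
                sum(x$sen_slope < 0, na.rm = TRUE), x$alpha,
                sum(x$mk_p < x$alpha, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.trend_map <- function(object, ...) object$sen_slope

#' @export
plot.trend_map <- function(x, ...) {
  graphics::image(x$lon, x$lat, t(x$sen_slope), xlab = "lon", ylab = "lat",
                  main = "Trend of block sensitivity (per year)",
                  col = grDevices::hcl.colors(21, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' @export
print.global_series <- function(x, ...) {
  cat(sprintf("<global_series> area-weighted %s over %d blocks\n", x$stat,
              length(x$values)))
  cat(sprintf("  MK Sen slope %.4g per year, p = %.3g%s\n", x$mk$sen_slope,
              x$mk$p_value, if (x$significant) sprintf(" (** p < %g)", x$alpha)
              else ""))
  invisible(x)
}

#' @export
plot.global_series <- function(x, ...) {
  graphics::plot(x$block_centers, x$values, type = "b", xlab = "block center year",
                 ylab = "change in sensitivity since first block",
                 main = sprintf("Global block sensitivity (MK p = %.3g)",
                                x$mk$p_value), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> %d cells, OOB R2 = %.3f\n", nrow(x$data), x$oob_r2))
  imp <- x$importance
  imp$share <- imp$mean_abs_shap / sum(imp$mean_abs_shap)
  print(imp, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.attribution <- function(x, ...) {
  imp <- x$importance[rev(seq_len(nrow(x$importance))), ]
  graphics::barplot(imp$mean_abs_shap, names.arg = imp$predictor, horiz = TRUE,
                    las = 1, xlab = "mean |SHAP|",
                    main = "Controls of sensitivity trends", ...)
  invisible(x)
}

#' @export
print.vegsens_run <- function(x, ...) {
  cat("<vegsens_run>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
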