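#' Calibrate satellite NDVI against field-measured NDVI
#'
#' Fits the four regression families with the satellite (MODIS) NDVI as
#' predictor and the field-spectrometer NDVI as response, and keeps the
#' best by R-squared / RMSE. This direction means the fitted model maps a
#' satellite raster onto the field-equivalent NDVI scale, which is what
#' "calibrating" the satellite product requires.
#'
#' @param plots plot table as produced by [aggregate_plot()] /
#'   [simulate_survey()]: must contain complete `modis_ndvi` and
#'   `mean_field_ndvi` columns for at least 3 plots.
#' @param by_type if `TRUE`, fit one calibration per grassland type and
#'   return a named list; default is a single pooled model.
#' @return An `ndvi_model` (or a list of two when `by_type = TRUE`).
#' @export
fit_calibration <- function(plots, by_type = FALSE) {
  need <- c("modis_ndvi", "mean_field_ndvi")
  if (!all(need %in% names(plots)))
    stop_gt("plot table lacks columns: %s",
            paste(setdiff(need, names(plots)), collapse = ", "),
            class = "gt_bad_arg")
  bad <- is.na(plots$modis_ndvi) | is.na(plots$mean_field_ndvi)
  if (any(bad))
    stop_gt("plots without paired NDVI values: %s",
            paste(utils::head(plots$plot_id[bad], 10), collapse = ", "),
            class = "gt_missing_pairs")
  if (by_type) {
    split_plots <- split(plots, plots$grassland_type)
    return(lapply(split_plots, fit_calibration, by_type = FALSE))
  }
  if (nrow(plots) < 3L)
    stop_gt("need >= 3 plots with paired NDVI, got %d", nrow(plots),
            class = "gt_bad_arg")
  fit_best_regression(plots$modis_ndvi, plots$mean_field_ndvi)
}

#' Apply an NDVI calibration to a raster stack
#'
#' Applies the calibration model per pixel and clips the result to the
#' NDVI definitional range \[-1, 1\]. Nodata propagates unchanged.
#'
#' @param stack an NDVI [raster_stack()].
#' @param model an `ndvi_model` from [fit_calibration()].
#' @return The calibrated NDVI `raster_stack`.
#' @export
apply_calibration <- function(stack, model) {
  v <- stack$values
  ok <- !is.na(v)
  if (model$family %in% c("log", "power") && any(v[ok] <= 0))
    stop_gt("calibration family '%s' undefined for %d non-positive pixels",
            model$family, sum(v[ok] <= 0), class = "gt_domain_error")
  v[ok] <- pmin(1, pmax(-1, family_predict(model$family, model$a, model$b,
                                           v[ok])))
  raster_stack(v, stack$times, stack$transform, "ndvi")
}
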