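#' Fit grassland-type-specific NDVI-to-AGB models
#'
#' For each grassland type separately, regresses plot AGB on field NDVI
#' over the four candidate families and keeps the best. Meadow and steppe
#' behave differently (different canopy structure, density and species),
#' so one model per type is the pipeline's unit of AGB estimation.
#'
#' @param plots plot table with `grassland_type`, `mean_field_ndvi`,
#'   `mean_agb_kg_per_hm2`; at least 3 plots per type.
#' @return An object of class `agb_model_set`: list with elements `meadow`
#'   and `steppe`, each an `ndvi_model` carrying `grassland_type`.
#' @export
fit_agb_models <- function(plots) {
  sets <- lapply(c(meadow = "meadow", steppe = "steppe"), function(tp) {
    sub <- plots[plots$grassland_type == tp &
                 !is.na(plots$mean_field_ndvi), , drop = FALSE]
    if (nrow(sub) < 3L)
      stop_gt("grassland type '%s' has %d usable plots; need >= 3",
              tp, nrow(sub), class = "gt_bad_arg")
    m <- fit_best_regression(sub$mean_field_ndvi, sub$mean_agb_kg_per_hm2)
    m$grassland_type <- tp
    m
  })
  structure(sets, class = "agb_model_set")
}

#' @export
print.agb_model_set <- function(x, ...) {
  cat("<NDVI-AGB model set>\n")
  for (tp in c("meadow", "steppe")) {
    cat(sprintf(" %s: ", tp)); print(x[[tp]])
  }
  invisible(x)
}

#' Estimate per-pixel AGB from calibrated NDVI
#'
#' Applies the type-specific NDVI-to-AGB model at every grassland pixel of
#' every layer. Non-grassland and nodata pixels become nodata. Negative
#' predictions (possible for linear models at very low NDVI) are floored
#' at 0, and pixels with NDVI above the saturation guard (0.8, the largest
#' NDVI seen in the survey) are still converted but counted, so silent
#' extrapolation stays visible. Both counts are returned in the `qa`
#' attribute as `list(n_floored, n_saturated)`.
#'
#' @param ndvi_stack calibrated NDVI [raster_stack()].
#' @param type_map integer matrix on the same grid: 1 = meadow,
#'   2 = steppe, 0 = non-grassland (NA also treated as non-grassland).
#' @param models an [fit_agb_models()] result.
#' @param ndvi_saturation NDVI value above which conversions are flagged.
#' @return An AGB `raster_stack` with attribute `qa`.
#' @export
estimate_agb <- function(ndvi_stack, type_map, models, ndvi_saturation = 0.8) {
  check_same_grid(ndvi_stack, type_map, "NDVI stack and type map")
  d <- dim(ndvi_stack$values)
  out <- array(NA_real_, d)
  tm <- array(type_map, d)       # recycle the type layer over time
  v <- ndvi_stack$values
  n_floored <- 0L
  for (code in c(1L, 2L)) {
    model <- models[[c("meadow", "steppe")[code]]]
    sel <- which(tm == code & !is.na(v))
    if (!length(sel)) next
    xv <- v[sel]
    if (model$family %in% c("log", "power")) {
      # non-positive NDVI has no biomass signal under these families
      pos <- xv > 0
      pred <- rep(0, length(xv))
      pred[pos] <- family_predict(model$family, model$a, model$b, xv[pos])
    } else {
      pred <- family_predict(model$family, model$a, model$b, xv)
    }
    n_floored <- n_floored + sum(pred < 0)
    out[sel] <- pmax(0, pred)
  }
  n_sat <- sum(!is.na(out) & v > ndvi_saturation, na.rm = TRUE)
  res <- raster_stack(out, ndvi_stack$times, ndvi_stack$transform, "agb")
  attr(res, "qa") <- list(n_floored = n_floored, n_saturated = n_sat)
  res
}

#' Flower-contamination sensitivity refit
#'
#' Large non-green flowers on top of the canopy bias the measured NDVI of
#' a plot, so the NDVI-AGB models are refitted after excluding plots whose
#' flower coverage exceeds the threshold, and the two model sets are
#' returned for comparison. The default threshold of 20% coverage is the
#' level treated as severe contamination.
#'
#' @param plots plot table with a complete `flower_coverage` column.
#' @param coverage_threshold exclusion threshold, fraction in \[0, 1\].
#' @return List of class `flower_sensitivity`: `original` and `refit`
#'   (both `agb_model_set`), plus `n_excluded` per type and the threshold.
#' @export
flower_sensitivity <- function(plots, coverage_threshold = 0.20) {
  check_number(coverage_threshold, "coverage_threshold", 0, 1)
  if (!"flower_coverage" %in% names(plots) || anyNA(plots$flower_coverage))
    stop_gt("flower_coverage must be present on every plot",
            class = "gt_bad_arg")
  keep <- plots$flower_coverage <= coverage_threshold
  excl <- plots[!keep, , drop = FALSE]
  structure(list(
    original = fit_agb_models(plots),
    refit = fit_agb_models(plots[keep, , drop = FALSE]),
    n_excluded = c(meadow = sum(excl$grassland_type == "meadow"),
                   steppe = sum(excl$grassland_type == "steppe")),
    coverage_threshold = coverage_threshold),
    class = "flower_sensitivity")
}

#' @export
print.flower_sensitivity <- function(x, ...) {
  cat(sprintf("<flower sensitivity, threshold %.0f%% coverage>\n",
              100 * x$coverage_threshold))
  cat(sprintf(" excluded: %d meadow, %d steppe plot(s)\n",
              x$n_excluded[["meadow"]], x$n_excluded[["steppe"]]))
  cat(" original:\n"); print(x$original)
  cat(" refit:\n"); print(x$refit)
  invisible(x)
}

#' Serialize / restore an AGB model set
#'
#' @param models an `agb_model_set`.
#' @param path JSON file path.
#' @return `read_agb_models()` returns the restored set.
#' @export
write_agb_models <- function(models, path) {
  payload <- lapply(models, function(m)
    c(m[c("family", "a", "b", "r_squared", "rmse", "n")],
      list(x_domain = m$x_domain, grassland_type = m$grassland_type)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_agb_models
#' @export
read_agb_models <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- lapply(p, function(m) {
    structure(list(family = m$family, a = m$a, b = m$b,
                   r_squared = m$r_squared, rmse = m$rmse,
                   n = as.integer(m$n), x_domain = as.numeric(m$x_domain),
                   grassland_type = m$grassland_type),
              class = "ndvi_model")
  })
  structure(sets, class = "agb_model_set")
}
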