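#' Run the full AGB-dynamics pipeline
#'
#' Executes the whole analysis in order: fit the NDVI calibration from
#' the plot table, fit the type-specific NDVI-to-AGB models, calibrate
#' the satellite NDVI stack, composite to annual layers by maximum value
#' (when the stack is sub-annual), optionally block-aggregate, convert to
#' AGB, classify per-pixel trends, estimate per-pixel Hurst exponents,
#' and combine both into the future-dynamics map. Every intermediate is
#' written under the output directory, plus a JSON manifest with a config
#' hash and per-stage summaries. Runs are deterministic: same config and
#' seed give byte-identical artifacts.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{plots}{plot table data frame, or path to a `plots.csv`.}
#'     \item{ndvi_stack}{NDVI [raster_stack()], or base path for
#'       [read_stack()].}
#'     \item{type_map}{integer type matrix (1 meadow / 2 steppe /
#'       0 non-grassland).}
#'     \item{out_dir}{output directory.}
#'     \item{trend_threshold}{slope threshold, default 10.}
#'     \item{tau_grid}{optional R/S window grid.}
#'     \item{flower_threshold}{contamination threshold, default 0.2.}
#'     \item{aggregation_factor}{block size, default 1 (no aggregation).}
#'     \item{paper_mode}{collapse the random class, default FALSE.}
#'     \item{seed}{integer seed, default 1.}
#'   }
#' @return The run manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(trend_threshold = 10, tau_grid = NULL,
                   flower_threshold = 0.2, aggregation_factor = 1,
                   paper_mode = FALSE, seed = 1L)
  config <- modifyList(defaults, config)
  for (f in c("plots", "ndvi_stack", "type_map", "out_dir"))
    if (is.null(config[[f]]))
      stop_gt("config lacks required entry '%s'", f, class = "gt_config_error")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  plots <- if (is.character(config$plots)) read.csv(config$plots)
           else config$plots
  stack <- if (is.character(config$ndvi_stack)) read_stack(config$ndvi_stack)
           else config$ndvi_stack
  type_map <- config$type_map
  manifest <- list(config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("grasstrend")),
                   stages = list(), artifacts = character())

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop_gt("stage '%s' failed: %s", name, conditionMessage(e),
              class = "gt_stage_failure"))
    res
  }

  calib <- stage("calibration", fit_calibration(plots))
  write_model(calib, file.path(out, "calib.json"))
  manifest$stages$calibration <- list(family = calib$family,
                                      r_squared = calib$r_squared)

  agb_models <- stage("agb_models", fit_agb_models(plots))
  write_agb_models(agb_models, file.path(out, "agb_models.json"))
  manifest$stages$agb_models <- lapply(agb_models, function(m)
    list(family = m$family, r_squared = m$r_squared, n = m$n))

  flower <- stage("flower_sensitivity",
                  flower_sensitivity(plots, config$flower_threshold))
  write_agb_models(flower$refit, file.path(out, "agb_models_refit.json"))
  manifest$stages$flower_sensitivity <-
    list(n_excluded = as.list(flower$n_excluded))

  ndvi_cal <- stage("apply_calibration", apply_calibration(stack, calib))
  annual_ndvi <- stage("annual_mvc",
                       if (all(stack$times == floor(stack$times))) ndvi_cal
                       else annual_mvc(ndvi_cal))
  if (config$aggregation_factor > 1) {
    annual_ndvi <- stage("aggregate",
                         aggregate_raster(annual_ndvi,
                                          config$aggregation_factor))
    type_map <- aggregate_types(type_map, config$aggregation_factor)
  }
  agb_annual <- stage("estimate_agb",
                      estimate_agb(annual_ndvi, type_map, agb_models))
  write_stack(agb_annual, file.path(out, "agb_annual"))
  manifest$stages$estimate_agb <- attr(agb_annual, "qa")

  trend <- stage("trend", trend_map(agb_annual,
                                    threshold = config$trend_threshold))
  write_matrix_csv(trend$slope, file.path(out, "slope.csv"))
  write_matrix_csv(class_codes(trend$trend_class, trend$class_levels),
                   file.path(out, "trend_classes.csv"))
  manifest$stages$trend <- as.list(round(trend$class_fractions, 6))

  hurst <- stage("hurst", hurst_map(agb_annual, tau_grid = config$tau_grid,
                                    type_map = type_map))
  write_matrix_csv(hurst$h, file.path(out, "hurst.csv"))
  write_matrix_csv(class_codes(hurst$sustainability, hurst$class_levels),
                   file.path(out, "sustainability.csv"))
  manifest$stages$hurst <- list(
    mean_h = hurst$mean_h,
    fraction_sustainable = hurst$fraction_sustainable)

  future <- stage("future", future_map(trend, hurst, type_map,
                                       paper_mode = config$paper_mode))
  write_matrix_csv(class_codes(future$classes, future$class_levels),
                   file.path(out, "future_classes.csv"))
  write.csv(future$fractions, file.path(out, "fractions.csv"),
            row.names = FALSE)
  manifest$stages$future <- list(
    improvement_pct =
      future$fractions$overall_pct[future$fractions$class == "improvement"],
    degradation_pct =
      future$fractions$overall_pct[future$fractions$class == "degradation"])

  manifest$artifacts <- c("calib.json", "agb_models.json",
                          "agb_models_refit.json", "agb_annual.csv",
                          "slope.csv", "trend_classes.csv", "hurst.csv",
                          "sustainability.csv", "future_classes.csv",
                          "fractions.csv")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config),
                         c("plots", "ndvi_stack", "type_map", "out_dir"))]
  paste0("cfg-", sum(utf8ToInt(
    jsonlite::toJSON(keep[order(names(keep))], auto_unbox = TRUE)) *
      seq_along(utf8ToInt(jsonlite::toJSON(keep[order(names(keep))],
                                           auto_unbox = TRUE)))) %% 1e9)
}

# majority type within each block, keeping grassland when present
aggregate_types <- function(type_map, factor) {
  nr <- ceiling(nrow(type_map) / factor)
  nc <- ceiling(ncol(type_map) / factor)
  ri <- ((seq_len(nrow(type_map)) - 1L) %/% factor) + 1L
  ci <- ((seq_len(ncol(type_map)) - 1L) %/% factor) + 1L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- type_map[ri == i, ci == j]
    block <- block[!is.na(block) & block > 0]
    if (length(block))
      out[i, j] <- as.integer(names(which.max(table(block))))
  }
  out
}

class_codes <- function(cls, levels) {
  matrix(match(as.character(cls), levels), nrow(cls), ncol(cls))
}

write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}
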