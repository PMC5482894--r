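#' Canopy reflectance spectrum
#'
#' Construct a `spectrum` object holding wavelength-indexed canopy
#' reflectance for one quadrat point. The red (680 nm) and near-infrared
#' (800 nm) bands must both be present because the narrow-band NDVI is
#' defined from them.
#'
#' @param wavelength_nm integer wavelengths in nanometres, strictly
#'   increasing; must include 680 and 800.
#' @param reflectance reflectance fractions in \[0, 1\], one per wavelength.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength_nm` and `reflectance`.
#' @examples
#' sp <- spectrum(c(400, 680, 800, 1000), c(0.05, 0.08, 0.45, 0.44))
#' compute_narrowband_ndvi(sp)
#' @export
spectrum <- function(wavelength_nm, reflectance) {
  if (length(wavelength_nm) != length(reflectance))
    stop_gt("wavelength and reflectance vectors differ in length (%d vs %d)",
            length(wavelength_nm), length(reflectance),
            class = "gt_bad_spectrum")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop_gt("wavelengths must be strictly increasing",
            class = "gt_bad_spectrum")
  if (anyNA(reflectance) || any(reflectance < 0 | reflectance > 1))
    stop_gt("reflectance values must lie in [0, 1]",
            class = "gt_bad_spectrum")
  if (!all(c(680, 800) %in% wavelength_nm))
    stop_gt("spectrum must cover the 680 nm and 800 nm bands",
            class = "gt_band_missing")
  structure(data.frame(wavelength_nm = as.numeric(wavelength_nm),
                       reflectance = as.numeric(reflectance)),
            class = c("spectrum", "data.frame"))
}

#' Narrow-band NDVI from a canopy spectrum
#'
#' Computes the field NDVI `(R800 - R680) / (R800 + R680)` where `R800` and
#' `R680` are the reflectances exactly at the 800 nm near-infrared and
#' 680 nm red wavelengths. No band averaging or interpolation is done: the
#' field spectrometer delivers 1 nm resolution, so the single-wavelength
#' values are used directly.
#'
#' @param spectrum a [spectrum()] object, or any data frame / list with
#'   `wavelength_nm` and `reflectance` components.
#' @return NDVI in \[-1, 1\].
#' @export
compute_narrowband_ndvi <- function(spectrum) {
  wl <- spectrum$wavelength_nm
  rf <- spectrum$reflectance
  i680 <- match(680, wl)
  i800 <- match(800, wl)
  if (is.na(i680) || is.na(i800))
    stop_gt("spectrum lacks the %s band(s) needed for NDVI",
            paste(c("680 nm", "800 nm")[c(is.na(i680), is.na(i800))],
                  collapse = " and "),
            class = "gt_band_missing")
  r680 <- rf[i680]
  r800 <- rf[i800]
  if (r680 + r800 <= 0)
    stop_gt("degenerate spectrum: R800 + R680 = 0, NDVI undefined",
            class = "gt_degenerate_spectrum")
  (r800 - r680) / (r800 + r680)
}

#' One sampled quadrat
#'
#' A quadrat is a 1 m x 1 m clip-harvest unit; nine of them make up a plot.
#' AGB is the oven-dry aboveground biomass of the quadrat in kg/hm2.
#' The spectrum is optional: some quadrats only contribute biomass.
#'
#' @param plot_id plot identifier (character or integer).
#' @param quadrat_index integer 1-9, unique within the plot.
#' @param agb_kg_per_hm2 non-negative biomass.
#' @param spectrum optional [spectrum()] object.
#' @return A list of class `quadrat_record`.
#' @export
quadrat_record <- function(plot_id, quadrat_index, agb_kg_per_hm2,
                           spectrum = NULL) {
  check_number(quadrat_index, "quadrat_index", 1, 9)
  check_number(agb_kg_per_hm2, "agb_kg_per_hm2", lower = 0)
  structure(list(plot_id = plot_id,
                 quadrat_index = as.integer(quadrat_index),
                 agb_kg_per_hm2 = agb_kg_per_hm2,
                 spectrum = spectrum),
            class = "quadrat_record")
}

#' Aggregate quadrats to a plot record
#'
#' Collapses the quadrats of one plot to the plot-level values used by all
#' downstream modelling: mean AGB over every quadrat, and mean field NDVI
#' over the quadrats that carry a spectrum. A plot whose quadrats have no
#' spectra at all gets `NA` NDVI (flagged, never zero-filled).
#'
#' @param quadrats list of [quadrat_record()] objects, all from one plot.
#' @param grassland_type `"meadow"` or `"steppe"`.
#' @param flower_coverage plot-level coverage fraction of large flowering
#'   species in \[0, 1\] (used by the contamination sensitivity analysis).
#' @param modis_ndvi optional paired satellite NDVI for the plot's pixel.
#' @return One-row data frame with columns `plot_id`, `grassland_type`,
#'   `mean_agb_kg_per_hm2`, `mean_field_ndvi`, `flower_coverage`,
#'   `modis_ndvi`, `n_quadrats`, `n_spectra`.
#' @export
aggregate_plot <- function(quadrats, grassland_type, flower_coverage = 0,
                           modis_ndvi = NA_real_) {
  if (length(quadrats) == 0L)
    stop_gt("no quadrats supplied", class = "gt_empty_plot")
  grassland_type <- match.arg(grassland_type, c("meadow", "steppe"))
  check_number(flower_coverage, "flower_coverage", 0, 1)
  ids <- unique(vapply(quadrats, function(q) as.character(q$plot_id), ""))
  if (length(ids) != 1L)
    stop_gt("quadrats come from several plots: %s",
            paste(ids, collapse = ", "), class = "gt_mixed_plots")
  qi <- vapply(quadrats, function(q) q$quadrat_index, 1L)
  if (anyDuplicated(qi))
    stop_gt("duplicate quadrat_index within plot %s", ids,
            class = "gt_duplicate_quadrat")
  agb <- vapply(quadrats, function(q) q$agb_kg_per_hm2, 0)
  ndvi <- vapply(quadrats, function(q) {
    if (is.null(q$spectrum)) NA_real_ else compute_narrowband_ndvi(q$spectrum)
  }, 0)
  data.frame(plot_id = ids,
             grassland_type = grassland_type,
             mean_agb_kg_per_hm2 = mean(agb),
             mean_field_ndvi = if (all(is.na(ndvi))) NA_real_
                               else mean(ndvi, na.rm = TRUE),
             flower_coverage = flower_coverage,
             modis_ndvi = modis_ndvi,
             n_quadrats = length(quadrats),
             n_spectra = sum(!is.na(ndvi)))
}
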