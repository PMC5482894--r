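#' Simulate fractional Gaussian noise
#'
#' Generates a zero-mean, unit-variance fractional Gaussian noise (fGn)
#' series with Hurst parameter `h` by circulant embedding of the exact
#' fGn autocovariance
#' `gamma(k) = 0.5 * (|k+1|^(2h) - 2|k|^(2h) + |k-1|^(2h))`
#' (the Davies-Harte construction). `h = 0.5` reduces to i.i.d. standard
#' Gaussian noise. If the embedding is numerically non-positive-definite
#' the generator falls back to the exact sequential conditional-Gaussian
#' (Durbin-Levinson) construction.
#'
#' fGn is the canonical stationary process with a defined Hurst exponent
#' (the increments of fractional Brownian motion), which makes it the
#' recovery oracle for the R/S estimator: a series simulated at `h` should
#' be estimated near `h`.
#'
#' @param n series length >= 2.
#' @param h Hurst parameter in (0, 1).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_fgn(512, 0.8, seed = 1)
#' @export
simulate_fgn <- function(n, h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drop(fgn_batch(n, h, 1L))
}

# batched fGn: one circulant embedding shared by `npix` independent series
# (columns). Uses the current RNG state.
fgn_batch <- function(n, h, npix) {
  n <- as.integer(n)
  if (n < 2L) stop_gt("n must be >= 2", class = "gt_bad_arg")
  check_number(h, "h")
  if (h <= 0 || h >= 1)
    stop_gt("h = %g outside (0, 1)", h, class = "gt_bad_arg")
  if (h == 0.5) return(matrix(rnorm(n * npix), n, npix))
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
  lam <- Re(fft(c(g, g[n:2])))
  if (min(lam) < -1e-8 * max(lam)) {
    return(vapply(seq_len(npix), function(j) hosking_fgn(n, h),
                  numeric(n)))
  }
  lam[lam < 0] <- 0
  m <- 2L * n
  w <- matrix(complex(real = 0, imaginary = 0), m, npix)
  w[1, ] <- sqrt(lam[1]) * rnorm(npix)
  w[n + 1, ] <- sqrt(lam[n + 1]) * rnorm(npix)
  u <- matrix(rnorm((n - 1L) * npix), n - 1L, npix)
  v <- matrix(rnorm((n - 1L) * npix), n - 1L, npix)
  half <- sqrt(lam[2:n] / 2)
  w[2:n, ] <- half * complex(real = 1) * u + half * complex(imaginary = 1) * v
  w[m:(n + 2L), ] <- Conj(w[2:n, , drop = FALSE])
  re <- Re(stats::mvfft(w)) / sqrt(m)
  re[seq_len(n), , drop = FALSE]
}

# exact O(n^2) sequential construction via the Durbin-Levinson recursion;
# fallback when the circulant embedding fails numerically.
hosking_fgn <- function(n, h) {
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
  x <- numeric(n)
  phi <- numeric(n)
  x[1] <- rnorm(1)
  v <- 1
  for (t in 1:(n - 1)) {
    if (t == 1) {
      phi[1] <- g[2]
    } else {
      prev <- phi[1:(t - 1)]
      phi[t] <- (g[t + 1] - sum(prev * g[t:2])) / v
      phi[1:(t - 1)] <- prev - phi[t] * rev(prev)
    }
    v <- v * (1 - phi[t]^2)
    mu <- sum(phi[1:t] * x[t:1])
    x[t + 1] <- mu + sqrt(v) * rnorm(1)
  }
  x
}

#' Survey generator configuration
#'
#' Defaults emulate the field campaign the pipeline is built around:
#' 31 meadow and 33 steppe plots of nine quadrats each; meadow NDVI in
#' (0.52, 0.78) and steppe NDVI in (0.12, 0.48), so the two types sit on
#' opposite sides of 0.5 and nothing exceeds the 0.8 saturation guard;
#' a linear meadow AGB law and a power steppe law whose expected plot
#' AGB over those NDVI ranges equals the surveyed type means of 706.7
#' and 498.7 kg/hm2;
#' quadrat AGB noise of 60 kg/hm2; a linear field-to-satellite map
#' `sat = 0.0556 + 1.1111 * field` (satellite NDVI reads slightly high)
#' with 0.01 noise; and 4 of 64 plots contaminated by large flowers,
#' which depress the measured NDVI by 0.05 at unchanged biomass.
#'
#' @param n_meadow_plots,n_steppe_plots plot counts.
#' @param meadow_law,steppe_law generating laws: `list(family, a, b)`.
#' @param meadow_ndvi_range,steppe_ndvi_range plot NDVI ranges.
#' @param agb_noise_sd quadrat AGB noise, kg/hm2.
#' @param ndvi_jitter_sd within-plot quadrat NDVI jitter.
#' @param calibration_a,calibration_b,calibration_noise_sd linear
#'   field-to-satellite NDVI map and its noise.
#' @param flower_fraction share of meadow plots contaminated.
#' @param contamination_ndvi_shift signed shift added to the measured
#'   NDVI of contaminated plots (negative: flowers mute the red-edge
#'   contrast).
#' @param seed integer seed; fixed seed gives identical output.
#' @return List of class `survey_config`.
#' @export
survey_config <- function(n_meadow_plots = 31L,
                          n_steppe_plots = 33L,
                          meadow_law = list(family = "linear",
                                            a = 121.7, b = 900),
                          steppe_law = list(family = "power",
                                            a = 4007, b = 1.8),
                          meadow_ndvi_range = c(0.52, 0.78),
                          steppe_ndvi_range = c(0.12, 0.48),
                          agb_noise_sd = 60,
                          ndvi_jitter_sd = 0.015,
                          calibration_a = 0.0556,
                          calibration_b = 1.1111,
                          calibration_noise_sd = 0.01,
                          flower_fraction = 4 / 64,
                          contamination_ndvi_shift = -0.05,
                          seed = 1L) {
  stopifnot(agb_noise_sd >= 0, ndvi_jitter_sd >= 0,
            calibration_noise_sd >= 0,
            flower_fraction >= 0, flower_fraction <= 1)
  structure(as.list(environment()), class = "survey_config")
}

# spectrum with a vegetation-like red edge whose exact values at 680 and
# 800 nm reproduce the target NDVI: R800 fixed at 0.5 and R680 solved
# from the NDVI formula (adjusted when the solution leaves [0, 1]).
make_spectrum_for_ndvi <- function(ndvi) {
  r800 <- 0.5
  r680 <- r800 * (1 - ndvi) / (1 + ndvi)
  if (r680 > 1 || r680 < 0) {
    r680 <- 0.8
    r800 <- r680 * (1 + ndvi) / (1 - ndvi)
    if (r800 > 1 || r800 < 0)
      stop_gt("no reflectance pair in [0,1] reproduces NDVI = %g", ndvi,
              class = "gt_bad_arg")
  }
  wl <- 400:1000
  rf <- ifelse(wl <= 680, r680,
               ifelse(wl >= 780, r800,
                      r680 + (r800 - r680) * (wl - 680) / 100))
  spectrum(wl, pmin(1, pmax(0, rf)))
}

#' Simulate a plot survey
#'
#' Generates the complete synthetic analogue of a clip-harvest field
#' survey: per-quadrat AGB and canopy spectra, and the aggregated plot
#' table with paired satellite NDVI. Per plot, a true NDVI is drawn from
#' the type's range; each of the nine quadrats gets a jittered NDVI, an
#' AGB value from the type's generating law plus Gaussian noise (floored
#' at 0), and a spectrum constructed to reproduce its *measured* NDVI
#' exactly. Contaminated plots carry `flower_coverage > 0.2` and their
#' measured NDVI is shifted by `contamination_ndvi_shift` while the
#' biomass still follows the true (unshifted) NDVI. The plot table is
#' produced by [aggregate_plot()], so every downstream invariant holds by
#' construction.
#'
#' @param config a [survey_config()].
#' @return List of class `survey`: `plots` (plot table with added truth
#'   columns `true_ndvi`, `contaminated`), `quadrats` (quadrat table), and
#'   `spectra` (named list of [spectrum()] objects, one per quadrat, names
#'   `"<plot_id>_q<index>"`).
#' @export
simulate_survey <- function(config = survey_config()) {
  set.seed(config$seed)
  plots <- list()
  quadrats <- list()
  spectra <- list()
  specs <- rbind(
    data.frame(type = "meadow", n = config$n_meadow_plots),
    data.frame(type = "steppe", n = config$n_steppe_plots))
  shift <- config$contamination_ndvi_shift
  for (r in seq_len(nrow(specs))) {
    tp <- specs$type[r]
    law <- if (tp == "meadow") config$meadow_law else config$steppe_law
    rng <- if (tp == "meadow") config$meadow_ndvi_range
           else config$steppe_ndvi_range
    n_contam <- if (tp == "meadow")
      round(config$flower_fraction * (config$n_meadow_plots +
                                      config$n_steppe_plots)) else 0L
    for (p in seq_len(specs$n[r])) {
      pid <- sprintf("%s_%02d", tp, p)
      contaminated <- tp == "meadow" && p <= n_contam
      lo <- rng[1]; hi <- rng[2]
      if (contaminated && shift != 0) {
        # keep the measured NDVI inside the type's range despite the shift
        lo <- min(hi - 0.01, lo + abs(shift) + 3 * config$ndvi_jitter_sd)
      }
      true_ndvi <- runif(1, lo, hi)
      qs <- vector("list", 9L)
      for (q in 1:9) {
        q_true <- min(0.8, max(1e-3,
          true_ndvi + rnorm(1, 0, config$ndvi_jitter_sd)))
        agb <- max(0, family_predict(law$family, law$a, law$b, q_true) +
                      rnorm(1, 0, config$agb_noise_sd))
        q_meas <- min(0.8, max(1e-3, q_true + if (contaminated) shift else 0))
        sp <- make_spectrum_for_ndvi(q_meas)
        key <- sprintf("%s_q%d", pid, q)
        spectra[[key]] <- sp
        qs[[q]] <- quadrat_record(pid, q, agb, sp)
        quadrats[[key]] <- data.frame(plot_id = pid, quadrat_index = q,
                                      agb_kg_per_hm2 = agb,
                                      ndvi_measured = q_meas,
                                      spectrum_file = paste0(key, ".csv"))
      }
      cov <- if (contaminated) runif(1, 0.25, 0.6) else runif(1, 0, 0.15)
      rec <- aggregate_plot(qs, tp, flower_coverage = cov)
      rec$modis_ndvi <- min(1, max(-1,
        config$calibration_a + config$calibration_b * rec$mean_field_ndvi +
          rnorm(1, 0, config$calibration_noise_sd)))
      rec$true_ndvi <- true_ndvi
      rec$contaminated <- contaminated
      plots[[pid]] <- rec
    }
  }
  structure(list(plots = do.call(rbind, c(plots, make.row.names = FALSE)),
                 quadrats = do.call(rbind, c(quadrats,
                                             make.row.names = FALSE)),
                 spectra = spectra,
                 config = config),
            class = "survey")
}

#' @export
print.survey <- function(x, ...) {
  tab <- table(x$plots$grassland_type)
  cat(sprintf("<synthetic survey> %d plots (%s), %d quadrats, %d spectra\n",
              nrow(x$plots),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$quadrats), length(x$spectra)))
  invisible(x)
}

#' Write / read a survey as CSV files
#'
#' Writes `plots.csv`, `quadrats.csv` and one two-column spectrum CSV per
#' quadrat under `dir/spectra/`. `read_survey()` restores the same
#' structure (without the generator truth columns' types changing).
#'
#' @param survey a [simulate_survey()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; `read_survey()` returns a `survey`-like list.
#' @export
write_survey <- function(survey, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(survey$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  write.csv(survey$quadrats, file.path(dir, "quadrats.csv"),
            row.names = FALSE)
  for (key in names(survey$spectra))
    write.csv(as.data.frame(survey$spectra[[key]]),
              file.path(dir, "spectra", paste0(key, ".csv")),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  plots <- read.csv(file.path(dir, "plots.csv"))
  quadrats <- read.csv(file.path(dir, "quadrats.csv"))
  files <- list.files(file.path(dir, "spectra"), pattern = "\\.csv$")
  spectra <- lapply(files, function(f) {
    df <- read.csv(file.path(dir, "spectra", f))
    spectrum(df$wavelength_nm, df$reflectance)
  })
  names(spectra) <- sub("\\.csv$", "", files)
  structure(list(plots = plots, quadrats = quadrats, spectra = spectra),
            class = "survey")
}

#' Stack generator configuration
#'
#' Defaults emulate the study-scale raster record at desk size: a 30 x 30
#' grid observed over 13 annual steps, pixel trends drawn from
#' N(3, 6) kg/hm2 per year (about 69% of pixels increasing), fractional
#' Gaussian noise with Hurst parameter 0.7 (persistent, near the surveyed
#' grassland average) scaled by 40 kg/hm2 around a 400 kg/hm2 baseline,
#' and the grid split into a meadow west half and steppe east half.
#'
#' @param n_rows,n_cols grid size.
#' @param n_years number of annual steps.
#' @param trend per-pixel trend, kg/hm2 per year: a single number
#'   (constant field) or `list(mean =, sd =)` for a Gaussian field.
#' @param hurst_target Hurst parameter of the noise, in (0, 1); a single
#'   number or a full matrix.
#' @param innovation_sd noise scale, kg/hm2.
#' @param baseline mean AGB level, kg/hm2 (must be non-negative).
#' @param type_layout `"halves"` (meadow west, steppe east), `"meadow"`,
#'   `"steppe"`, or an integer matrix (1/2/0).
#' @param sixteen_day also emit a within-year 23-step stack whose annual
#'   maximum equals the annual value exactly (to exercise compositing)?
#' @param seasonal_amplitude depth of the within-year seasonal dip.
#' @param start_year first year label.
#' @param seed integer seed.
#' @return List of class `stack_config`.
#' @export
stack_config <- function(n_rows = 30L, n_cols = 30L, n_years = 13L,
                         trend = list(mean = 3, sd = 6),
                         hurst_target = 0.7,
                         innovation_sd = 40,
                         baseline = 400,
                         type_layout = "halves",
                         sixteen_day = FALSE,
                         seasonal_amplitude = 100,
                         start_year = 2000L,
                         seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_years >= 2, innovation_sd >= 0)
  if (baseline < 0)
    stop_gt("baseline AGB must be non-negative", class = "gt_bad_arg")
  structure(as.list(environment()), class = "stack_config")
}

#' Simulate an annual AGB raster stack with known trend and memory
#'
#' Each pixel's series is `baseline + trend * i + innovation_sd * fGn(h)`
#' for year index `i = 1..n_years`: an additive linear trend over
#' fractional Gaussian noise, so both the trend slope and the Hurst
#' exponent of every pixel are known exactly and recovery can be tested.
#' With `sixteen_day = TRUE` the result also carries a 23-step-per-year
#' stack whose within-year seasonal curve peaks at exactly the annual
#' value, so annual maximum-value compositing reproduces the annual stack.
#'
#' @param config a [stack_config()].
#' @return List of class `synthetic_stack`: `stack` (annual
#'   [raster_stack()], variable `"agb"`), `type_map` (integer matrix),
#'   `truth` (data frame `row`, `col`, `type`, `trend`, `hurst`), and
#'   `sixteen_day` (a `raster_stack` or `NULL`).
#' @export
simulate_stack <- function(config = stack_config()) {
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols; ny <- config$n_years
  npix <- nr * nc
  trend <- if (is.list(config$trend)) {
    rnorm(npix, config$trend$mean, config$trend$sd)
  } else rep(as.numeric(config$trend), npix)
  hmat <- if (is.matrix(config$hurst_target)) as.vector(config$hurst_target)
          else rep(config$hurst_target, npix)
  vals <- matrix(NA_real_, ny, npix)
  for (h in unique(hmat)) {
    sel <- which(hmat == h)
    vals[, sel] <- fgn_batch(ny, h, length(sel))
  }
  i <- seq_len(ny)
  series <- config$baseline + outer(i, trend) + config$innovation_sd * vals
  years <- config$start_year + i - 1L
  annual <- raster_stack(array(t(series), c(nr, nc, ny)), years,
                         variable = "agb")
  type_map <- switch(
    as.character(config$type_layout[1]),
    halves = matrix(rep(c(1L, 2L), times = c(floor(nc / 2),
                                             ceiling(nc / 2))),
                    nr, nc, byrow = TRUE),
    meadow = matrix(1L, nr, nc),
    steppe = matrix(2L, nr, nc),
    {
      if (!is.matrix(config$type_layout))
        stop_gt("unknown type_layout", class = "gt_bad_arg")
      config$type_layout
    })
  sub <- NULL
  if (config$sixteen_day) {
    np <- 23L
    w <- sin(pi * (seq_len(np) - 0.5) / np)^2   # peaks at exactly 1
    sub_vals <- array(NA_real_, c(nr, nc, ny * np))
    times <- numeric(ny * np)
    for (y in seq_len(ny)) {
      ann <- annual$values[, , y]
      for (j in seq_len(np)) {
        k <- (y - 1L) * np + j
        sub_vals[, , k] <- ann - config$seasonal_amplitude * (1 - w[j])
        times[k] <- years[y] + (j - 1) / np
      }
    }
    sub <- raster_stack(sub_vals, times, variable = "agb")
  }
  structure(list(stack = annual,
                 type_map = type_map,
                 truth = data.frame(
                   row = rep(seq_len(nr), times = nc),
                   col = rep(seq_len(nc), each = nr),
                   type = as.vector(type_map),
                   trend = trend,
                   hurst = hmat),
                 sixteen_day = sub,
                 config = config),
            class = "synthetic_stack")
}
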