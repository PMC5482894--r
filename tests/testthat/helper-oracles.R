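# shared oracles and fixture builders, independent of the code paths they
# check

# minimal spectrum with prescribed band reflectances
band_spectrum <- function(r680, r800) {
  spectrum(c(600, 680, 750, 800), c(r680, r680, (r680 + r800) / 2, r800))
}

# textbook OLS slope via moments -- oracle for the sum-form slope
ols_slope_oracle <- function(y) {
  i <- seq_along(y)
  stats::cov(i, y) / stats::var(i)
}

# closed-form simple OLS (a, b) from the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  c(a = (sum(y) - b * sum(x)) / n, b = b)
}

# brute-force per-pixel annual maximum
mvc_oracle <- function(stack) {
  years <- floor(stack$times)
  uy <- sort(unique(years))
  d <- dim(stack$values)
  out <- array(NA_real_, c(d[1], d[2], length(uy)))
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_along(uy)) {
      v <- stack$values[i, j, years == uy[k]]
      if (!all(is.na(v))) out[i, j, k] <- max(v, na.rm = TRUE)
    }
  out
}

# tiny plot table with exact AGB laws, for model-recovery checks
exact_plot_table <- function(meadow_law = c(a = 200, b = 900),
                             steppe_law = c(a = 1200, b = 1.8),
                             n_per_type = 8) {
  nd_m <- seq(0.52, 0.78, length.out = n_per_type)
  nd_s <- seq(0.12, 0.48, length.out = n_per_type)
  data.frame(
    plot_id = c(paste0("m", seq_len(n_per_type)),
                paste0("s", seq_len(n_per_type))),
    grassland_type = rep(c("meadow", "steppe"), each = n_per_type),
    mean_field_ndvi = c(nd_m, nd_s),
    mean_agb_kg_per_hm2 = c(meadow_law["a"] + meadow_law["b"] * nd_m,
                            steppe_law["a"] * nd_s^steppe_law["b"]),
    flower_coverage = 0,
    modis_ndvi = NA_real_)
}
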