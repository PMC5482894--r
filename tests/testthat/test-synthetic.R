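test_that("fGn is reproducible, unit-scale, and white at h = 0.5", {
  a <- simulate_fgn(256, 0.7, seed = 5)
  b <- simulate_fgn(256, 0.7, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_fgn(100, 1.2), class = "gt_bad_arg")
  expect_error(simulate_fgn(1, 0.5), class = "gt_bad_arg")

  set.seed(61)
  x <- simulate_fgn(4096, 0.5)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(4096))
  expect_lt(abs(sd(x) - 1), 0.1)
})

test_that("persistent fGn shows positive lag-1 autocorrelation", {
  set.seed(67)
  pos <- replicate(100, {
    x <- simulate_fgn(2048, 0.9)
    cor(x[-1], x[-length(x)]) > 0
  })
  expect_gte(mean(pos), 0.95)
})

test_that("the sequential fallback generator matches the fGn covariance", {
  set.seed(71)
  acfs <- replicate(40, {
    x <- grasstrend:::hosking_fgn(256, 0.8)
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  })
  gamma1 <- 0.5 * (2^(2 * 0.8) - 2)     # theoretical lag-1 autocovariance
  expect_lt(abs(mean(acfs) - gamma1), 0.1)
})

test_that("survey spectra invert exactly to their measured NDVI", {
  sv <- simulate_survey(survey_config(seed = 3))
  keys <- names(sv$spectra)
  got <- vapply(sv$spectra, compute_narrowband_ndvi, 0)
  want <- sv$quadrats$ndvi_measured[
    match(keys, sprintf("%s_q%d", sv$quadrats$plot_id,
                        sv$quadrats$quadrat_index))]
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("meadow and steppe plots fall on their sides of NDVI 0.5", {
  sv <- simulate_survey(survey_config(seed = 13))
  m <- sv$plots$grassland_type == "meadow"
  expect_true(all(sv$plots$mean_field_ndvi[m] > 0.5))
  expect_true(all(sv$plots$mean_field_ndvi[!m] < 0.5))
  expect_true(all(sv$plots$mean_field_ndvi <= 0.8))
})

test_that("a degenerate noiseless survey reproduces its law exactly", {
  cfg <- survey_config(n_meadow_plots = 3L, n_steppe_plots = 3L,
                       meadow_law = list(family = "linear", a = 200,
                                         b = 900),
                       meadow_ndvi_range = c(0.6, 0.6),
                       agb_noise_sd = 0, ndvi_jitter_sd = 0,
                       calibration_noise_sd = 0,
                       flower_fraction = 0, seed = 1)
  sv <- simulate_survey(cfg)
  m <- sv$plots[sv$plots$grassland_type == "meadow", ]
  expect_true(all(abs(m$mean_agb_kg_per_hm2 - 740) < 1e-9))
  expect_true(all(abs(sv$quadrats$agb_kg_per_hm2[
    grepl("meadow", sv$quadrats$plot_id)] - 740) < 1e-9))
})

test_that("surveys are deterministic under a fixed seed and round-trip", {
  s1 <- simulate_survey(survey_config(seed = 29))
  s2 <- simulate_survey(survey_config(seed = 29))
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$quadrats, s2$quadrats)

  dir <- tempfile()
  write_survey(s1, dir)
  back <- read_survey(dir)
  expect_equal(back$plots$mean_field_ndvi, s1$plots$mean_field_ndvi)
  expect_equal(nrow(back$quadrats), nrow(s1$quadrats))
  key <- names(s1$spectra)[1]
  expect_equal(back$spectra[[key]]$reflectance,
               s1$spectra[[key]]$reflectance)
})

test_that("generated surveys satisfy the consuming modules' contracts", {
  sv <- simulate_survey(survey_config(seed = 41))
  expect_s3_class(fit_calibration(sv$plots), "ndvi_model")
  expect_s3_class(fit_agb_models(sv$plots), "agb_model_set")
  expect_s3_class(flower_sensitivity(sv$plots), "flower_sensitivity")
})

test_that("noiseless stacks carry their trend exactly", {
  sim <- simulate_stack(stack_config(n_rows = 5, n_cols = 5, trend = 4,
                                     innovation_sd = 0, seed = 11))
  tr <- trend_map(sim$stack)
  expect_true(all(abs(tr$slope - 4) < 1e-9))
})

test_that("trend-free white-noise stacks split near 50/50 by direction", {
  sim <- simulate_stack(stack_config(n_rows = 40, n_cols = 40, trend = 0,
                                     hurst_target = 0.5,
                                     innovation_sd = 30, seed = 73))
  tr <- trend_map(sim$stack)
  up <- mean(tr$slope >= 0)
  expect_lt(abs(up - 0.5), 3 * 0.5 / sqrt(1600))
})

test_that("the 16-day stack's annual composite equals the annual truth", {
  sim <- simulate_stack(stack_config(n_rows = 4, n_cols = 4, n_years = 5,
                                     sixteen_day = TRUE, seed = 31))
  mv <- annual_mvc(sim$sixteen_day)
  expect_equal(mv$values, sim$stack$values, tolerance = 1e-12)
  expect_equal(mv$times, sim$stack$times)
})

test_that("stacks are deterministic and carry matching truth tables", {
  s1 <- simulate_stack(stack_config(n_rows = 6, n_cols = 7, seed = 19))
  s2 <- simulate_stack(stack_config(n_rows = 6, n_cols = 7, seed = 19))
  expect_identical(s1$stack$values, s2$stack$values)
  expect_equal(nrow(s1$truth), 42)
  expect_equal(dim(s1$type_map), c(6, 7))
  expect_true(all(s1$type_map %in% c(0L, 1L, 2L)))
  expect_error(simulate_stack(stack_config(baseline = -5)),
               class = "gt_bad_arg")
})
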