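test_that("noiseless generating laws are recovered per type", {
  plots <- exact_plot_table(meadow_law = c(a = 200, b = 900),
                            steppe_law = c(a = 1200, b = 1.8))
  ms <- fit_agb_models(plots)
  expect_equal(ms$meadow$family, "linear")
  expect_equal(unname(coef(ms$meadow)), c(200, 900), tolerance = 1e-6)
  expect_equal(ms$meadow$r_squared, 1, tolerance = 1e-9)
  expect_equal(ms$steppe$family, "power")
  expect_equal(unname(coef(ms$steppe)), c(1200, 1.8), tolerance = 1e-5)
  expect_error(fit_agb_models(plots[plots$grassland_type == "meadow", ]),
               class = "gt_bad_arg")
})

test_that("steppe power law wins and its exponent is recovered under noise", {
  set.seed(2)
  fams <- character(100)
  bs <- numeric(100)
  for (r in 1:100) {
    ndvi <- runif(33, 0.12, 0.48)
    agb <- pmax(0, 1200 * ndvi^1.8 + rnorm(33, 0, 30))
    plots <- data.frame(plot_id = seq_len(33), grassland_type = "steppe",
                        mean_field_ndvi = ndvi, mean_agb_kg_per_hm2 = agb)
    m <- fit_best_regression(plots$mean_field_ndvi,
                             plots$mean_agb_kg_per_hm2)
    fams[r] <- m$family
    bs[r] <- if (m$family == "power") m$b else NA
  }
  # the exponential family is a close competitor on the narrow steppe
  # NDVI range, so power is the clear modal choice rather than a
  # near-certain one
  expect_gte(mean(fams == "power"), 0.6)
  expect_gt(mean(fams == "power"),
            max(mean(fams == "linear"), mean(fams == "exponential"),
                mean(fams == "log")))
  expect_lt(abs(median(bs, na.rm = TRUE) - 1.8), 0.2)
})

test_that("AGB estimation applies the right model per pixel and masks", {
  models <- structure(list(
    meadow = structure(list(family = "linear", a = 200, b = 900,
                            grassland_type = "meadow"),
                       class = "ndvi_model"),
    steppe = structure(list(family = "power", a = 1200, b = 1.8,
                            grassland_type = "steppe"),
                       class = "ndvi_model")), class = "agb_model_set")

  u <- raster_stack(array(0.6, c(3, 3, 2)), 1:2, variable = "ndvi")
  allm <- matrix(1L, 3, 3)
  est <- estimate_agb(u, allm, models)
  expect_true(all(est$values == 200 + 900 * 0.6))

  tm <- matrix(c(1L, 2L, 0L), 3, 3)
  v <- array(runif(3 * 3 * 2, 0.1, 0.7), c(3, 3, 2))
  st <- raster_stack(v, 1:2, variable = "ndvi")
  mixed <- estimate_agb(st, tm, models)
  expect_true(all(is.na(mixed$values[tm == 0L])))
  # two-pass oracle: each type estimated alone then mosaicked
  m_only <- estimate_agb(st, ifelse(tm == 1L, 1L, 0L), models)
  s_only <- estimate_agb(st, ifelse(tm == 2L, 2L, 0L), models)
  oracle <- ifelse(array(tm == 1L, dim(v)), m_only$values, s_only$values)
  expect_equal(mixed$values, oracle)

  expect_error(estimate_agb(st, matrix(1L, 2, 2), models),
               class = "gt_grid_mismatch")
})

test_that("AGB output is non-negative and flags floored/saturated pixels", {
  dropping <- structure(list(
    meadow = structure(list(family = "linear", a = -100, b = 200),
                       class = "ndvi_model"),
    steppe = structure(list(family = "linear", a = -100, b = 200),
                       class = "ndvi_model")), class = "agb_model_set")
  v <- array(c(0.1, 0.9, 0.3, 0.85), c(2, 2, 1))
  st <- raster_stack(v, 1, variable = "ndvi")
  est <- estimate_agb(st, matrix(1L, 2, 2), dropping)
  expect_true(all(est$values >= 0, na.rm = TRUE))
  qa <- attr(est, "qa")
  expect_equal(qa$n_floored, 2)    # 0.1 and 0.3 predict below zero
  expect_equal(qa$n_saturated, 2)  # 0.9 and 0.85 exceed the 0.8 guard
})

test_that("monotone models preserve NDVI ordering within a type", {
  plots <- exact_plot_table()
  ms <- fit_agb_models(plots)
  ndvi <- sort(runif(20, 0.2, 0.45))
  pred <- predict(ms$steppe, ndvi)
  expect_true(all(diff(pred) > 0))
})

test_that("flower refit is a no-op without contamination and strict at 0", {
  plots <- exact_plot_table()
  plots$flower_coverage <- rep(c(0.05, 0.1), length.out = nrow(plots))
  fs <- flower_sensitivity(plots, 0.20)
  expect_equal(coef(fs$refit$meadow), coef(fs$original$meadow))
  expect_equal(sum(fs$n_excluded), 0)

  # threshold 0 excludes every plot with any flowers at all
  some <- plots
  some$flower_coverage <- rep(c(0, 0.02), length.out = nrow(some))
  fs0 <- flower_sensitivity(some, 0)
  expect_equal(sum(fs0$n_excluded), sum(some$flower_coverage > 0))
  # exclusion that starves a type below 3 plots is an error
  few <- plots
  few$flower_coverage <- ifelse(few$grassland_type == "meadow", 0.5, 0)
  expect_error(flower_sensitivity(few, 0.2), class = "gt_bad_arg")
})

test_that("excluding flower-contaminated plots lowers meadow predictions", {
  sv <- simulate_survey(survey_config(seed = 17))
  fs <- flower_sensitivity(sv$plots, 0.20)
  expect_gt(sum(fs$n_excluded), 0)
  at <- seq(0.55, 0.75, by = 0.05)
  expect_true(all(predict(fs$refit$meadow, at) <
                  predict(fs$original$meadow, at)))
})

test_that("AGB model sets survive a JSON round trip", {
  ms <- fit_agb_models(exact_plot_table())
  path <- tempfile(fileext = ".json")
  write_agb_models(ms, path)
  ms2 <- read_agb_models(path)
  expect_equal(coef(ms2$meadow), coef(ms$meadow), tolerance = 1e-12)
  expect_equal(ms2$steppe$family, ms$steppe$family)
  expect_equal(ms2$steppe$grassland_type, "steppe")
})
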