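test_that("the stack container validates shape, times, and NDVI bounds", {
  v <- array(0.5, c(3, 3, 2))
  expect_s3_class(raster_stack(v, 1:2, variable = "ndvi"), "raster_stack")
  expect_error(raster_stack(v, 1:3, variable = "ndvi"),
               class = "gt_bad_raster")
  expect_error(raster_stack(v, c(2, 1), variable = "ndvi"),
               class = "gt_bad_raster")
  expect_error(raster_stack(array(1.5, c(2, 2, 1)), 1, variable = "ndvi"),
               class = "gt_bad_raster")
  # AGB stacks are not bounded
  expect_s3_class(raster_stack(array(1500, c(2, 2, 1)), 1,
                               variable = "agb"), "raster_stack")
})

test_that("annual compositing takes the per-year maximum and keeps nodata", {
  v <- array(NA_real_, c(1, 1, 3))
  v[1, 1, ] <- c(0.1, 0.5, 0.3)
  st <- raster_stack(v, 2000 + (0:2) / 23, variable = "ndvi")
  out <- annual_mvc(st)
  expect_equal(dim(out$values)[3], 1)
  expect_equal(out$values[1, 1, 1], 0.5)

  v2 <- array(NA_real_, c(2, 1, 3))
  v2[1, 1, ] <- c(0.2, NA, 0.4)
  st2 <- raster_stack(v2, 2000 + (0:2) / 23, variable = "ndvi")
  out2 <- annual_mvc(st2)
  expect_equal(out2$values[1, 1, 1], 0.4)
  expect_true(is.na(out2$values[2, 1, 1]))
})

test_that("compositing matches the brute-force maximum and is idempotent", {
  set.seed(3)
  v <- array(runif(4 * 5 * 46, -0.1, 0.9), c(4, 5, 46))
  v[sample(length(v), 40)] <- NA
  times <- rep(2000:2001, each = 23) + rep((0:22) / 23, times = 2)
  st <- raster_stack(v, times, variable = "ndvi")
  out <- annual_mvc(st)
  expect_equal(out$values, mvc_oracle(st))
  expect_equal(out$times, c(2000, 2001))
  # every composite value is one of (and >= all of) its inputs
  again <- annual_mvc(out)
  expect_equal(again$values, out$values)
  expect_equal(again$times, out$times)
})

test_that("block aggregation averages blocks and rescales the transform", {
  expect_equal(aggregate_raster(
    raster_stack(array(0.5, c(4, 4, 1)), 1, variable = "ndvi"), 1)$values,
    array(0.5, c(4, 4, 1)))

  m <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)   # one 2x2 block
  st <- raster_stack(array(m, c(2, 2, 1)), 1, variable = "ndvi")
  ag <- aggregate_raster(st, 2)
  expect_equal(dim(ag$values), c(1, 1, 1))
  expect_equal(ag$values[1, 1, 1], 0.5)
  expect_equal(ag$transform[3:4], st$transform[3:4] * 2)

  expect_error(aggregate_raster(st, 0), class = "gt_bad_arg")
})

test_that("mean aggregation conserves the global mean without nodata", {
  set.seed(8)
  v <- array(runif(40 * 40), c(40, 40, 1))
  st <- raster_stack(v, 1, variable = "ndvi")
  ag <- aggregate_raster(st, 10)
  expect_equal(mean(ag$values), mean(v), tolerance = 1e-10)
})

test_that("aggregation handles edges, nodata blocks, and other statistics", {
  v <- array(seq(0, 1, length.out = 5 * 3), c(5, 3, 1))
  v[1:2, 1, 1] <- NA
  st <- raster_stack(v, 1, variable = "ndvi")
  ag <- aggregate_raster(st, 2)
  expect_equal(dim(ag$values)[1:2], c(3, 2))
  # top-left block is all-NA in col 1 only if both cells NA; here the block
  # spans cols 1:2 so the valid cells average
  block <- v[1:2, 1:2, 1]
  expect_equal(ag$values[1, 1, 1], mean(block[!is.na(block)]))

  allna <- array(NA_real_, c(2, 2, 1))
  stna <- raster_stack(allna, 1, variable = "ndvi")
  expect_true(is.na(aggregate_raster(stna, 2)$values[1, 1, 1]))

  agmax <- aggregate_raster(st, 2, stat = "max")
  expect_equal(agmax$values[1, 1, 1], max(block, na.rm = TRUE))
})

test_that("stacks survive the text round trip", {
  set.seed(12)
  v <- array(runif(3 * 4 * 2, -0.5, 0.9), c(3, 4, 2))
  v[2, 2, 1] <- NA
  st <- raster_stack(v, c(2000, 2001),
                     transform = c(100, 200, 1, 1), variable = "ndvi")
  base <- tempfile()
  write_stack(st, base)
  st2 <- read_stack(base)
  expect_equal(st2$values, st$values)
  expect_equal(st2$times, st$times)
  expect_equal(st2$transform, st$transform)
  expect_equal(st2$variable, st$variable)
})
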