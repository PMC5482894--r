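test_that("linear fit reproduces an exact line and the OLS closed form", {
  m <- fit_regression(c(1, 2, 3), c(3, 5, 7), "linear")
  expect_equal(coef(m), c(a = 1, b = 2), tolerance = 1e-12)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0, tolerance = 1e-12)

  x <- c(1, 2, 3, 4); y <- c(2.1, 3.9, 6.2, 7.8)
  m2 <- fit_regression(x, y, "linear")
  oracle <- ols_oracle(x, y)
  expect_equal(coef(m2), oracle, tolerance = 1e-10)
  res <- y - (oracle["a"] + oracle["b"] * x)
  expect_equal(m2$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(m2$rmse, sqrt(sum(res^2) / 4), tolerance = 1e-10)
})

test_that("each family recovers itself exactly from noiseless data", {
  x <- c(0.8, 1.5, 2.2, 3.1, 4.0)
  gens <- list(linear = function(x) 1.5 + 2 * x,
               exponential = function(x) 2 * exp(0.4 * x),
               log = function(x) 3 + 1.2 * log(x),
               power = function(x) 2 * x^1.3)
  truth <- list(linear = c(1.5, 2), exponential = c(2, 0.4),
                log = c(3, 1.2), power = c(2, 1.3))
  for (fam in names(gens)) {
    m <- fit_regression(x, gens[[fam]](x), fam)
    expect_equal(unname(coef(m)), truth[[fam]], tolerance = 1e-6)
    expect_equal(m$r_squared, 1, tolerance = 1e-9)
    expect_lt(m$rmse, 1e-6)
  }
  # exact power law through integer points
  mp <- fit_regression(c(1, 2, 4), c(2, 4, 8), "power")
  expect_equal(unname(coef(mp)), c(2, 1), tolerance = 1e-8)
})

test_that("prediction applies the family formula and guards its domain", {
  lin <- fit_regression(1:3, c(3, 5, 7), "linear")
  expect_equal(predict(lin, 0), 1)
  pw <- structure(list(family = "power", a = 3, b = 0),
                  class = "ndvi_model")
  expect_equal(predict(pw, c(1, 7, 100)), c(3, 3, 3))
  ex <- structure(list(family = "exponential", a = 2, b = log(2)),
                  class = "ndvi_model")
  expect_equal(predict(ex, 3), 16)
  expect_error(predict(pw, c(1, -2)), class = "gt_domain_error")
})

test_that("model selection maximizes R2 with RMSE and simplicity tie-breaks", {
  mk <- function(family, r2, rmse)
    structure(list(family = family, r_squared = r2, rmse = rmse),
              class = "ndvi_model")
  expect_equal(select_best(list(mk("linear", 0.74, 1),
                                mk("power", 0.63, 2)))$family, "linear")
  expect_equal(select_best(list(A = mk("power", 0.9, 5),
                                B = mk("log", 0.9, 4)))$family, "log")
  expect_equal(select_best(list(mk("log", 0.9, 4),
                                mk("linear", 0.9, 4)))$family, "linear")
  expect_error(select_best(list()), class = "gt_bad_arg")

  # noiseless linear data: the linear family must win the 4-way contest
  x <- c(1, 2, 3, 5, 8)
  best <- fit_best_regression(x, 2 + 3 * x)
  expect_equal(best$family, "linear")
})

test_that("linear R2 equals the squared Pearson correlation", {
  set.seed(11)
  for (k in 1:20) {
    x <- runif(15, 1, 5)
    y <- 2 + x + rnorm(15, 0, 0.5)
    m <- fit_regression(x, y, "linear")
    expect_equal(m$r_squared, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("RMSE shrinks (weakly) with the noise level", {
  set.seed(5)
  x <- runif(60, 1, 4)
  eps <- rnorm(60)
  rmses <- sapply(c(2, 1, 0.3, 0), function(s)
    fit_regression(x, 1 + 2 * x + s * eps, "linear")$rmse)
  expect_true(all(diff(rmses) <= 1e-12))
})

test_that("fits reject invalid input", {
  expect_error(fit_regression(c(-1, 2, 3), c(1, 2, 3), "power"),
               class = "gt_domain_error")
  expect_error(fit_regression(c(0, 2, 3), c(1, 2, 3), "log"),
               class = "gt_domain_error")
  expect_error(fit_regression(c(2, 2, 2), c(1, 2, 3), "linear"),
               class = "gt_singular_fit")
  expect_error(fit_regression(1:2, 1:2, "linear"), class = "gt_bad_arg")
})

test_that("models survive a JSON round trip", {
  m <- fit_regression(c(0.1, 0.3, 0.5, 0.7), c(10, 28, 55, 70), "power")
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$family, m$family)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(m2$x_domain, m$x_domain)
  expect_equal(predict(m2, 0.4), predict(m, 0.4))
})
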