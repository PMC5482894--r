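#' Fit one of the four candidate regression families
#'
#' Fits one of the regression families used throughout the pipeline for
#' NDVI calibration and NDVI-to-AGB modelling:
#' \describe{
#'   \item{linear}{`y = a + b * x`, ordinary least squares.}
#'   \item{exponential}{`y = a * exp(b * x)`, nonlinear least squares.}
#'   \item{log}{`y = a + b * ln(x)`, least squares on `ln(x)`.}
#'   \item{power}{`y = a * x^b`, nonlinear least squares.}
#' }
#' Nonlinear families are fitted by Levenberg-Marquardt least squares in
#' the original response space, initialized from the log-transform closed
#' form, so that the goodness-of-fit statistics are comparable across
#' families. `R^2 = 1 - SS_res/SS_tot` and `RMSE = sqrt(SS_res / n)`
#' (divisor `n`, not `n - p`; see `rmse_divisor`) are both computed on the
#' original scale for every family.
#'
#' @param x,y numeric vectors of equal length >= 3. `x` must be strictly
#'   positive for the `log` and `power` families.
#' @param family one of `"linear"`, `"exponential"`, `"log"`, `"power"`.
#' @param rmse_divisor `"n"` (default) or `"n-p"`; divisor of SS_res in the
#'   RMSE.
#' @return An object of class `ndvi_model`: a list with elements `family`,
#'   `a`, `b`, `r_squared`, `rmse`, `n`, `x_domain` (observed range of
#'   `x`), usable with [predict()], [coef()], [print()] and [summary()].
#' @examples
#' m <- fit_regression(c(1, 2, 3), c(3, 5, 7), "linear")
#' coef(m)                      # a = 1, b = 2
#' predict(m, 10)               # 21
#' @seealso [select_best()], [fit_calibration()], [fit_agb_models()]
#' @export
fit_regression <- function(x, y,
                           family = c("linear", "exponential", "log", "power"),
                           rmse_divisor = c("n", "n-p")) {
  family <- match.arg(family)
  rmse_divisor <- match.arg(rmse_divisor)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_gt("x and y differ in length (%d vs %d)", length(x), length(y),
            class = "gt_bad_arg")
  if (anyNA(x) || anyNA(y))
    stop_gt("x and y must be complete (no NA)", class = "gt_bad_arg")
  n <- length(x)
  if (n < 3L)
    stop_gt("need at least 3 observations, got %d", n, class = "gt_bad_arg")
  if (family %in% c("log", "power") && any(x <= 0))
    stop_gt("family '%s' requires strictly positive x (%d offending values)",
            family, sum(x <= 0), class = "gt_domain_error")
  if (var(x) == 0)
    stop_gt("degenerate predictor: all x equal", class = "gt_singular_fit")

  ab <- switch(family,
    linear = {
      f <- lm(y ~ x)
      c(a = unname(coef(f)[1]), b = unname(coef(f)[2]))
    },
    log = {
      f <- lm(y ~ log(x))
      c(a = unname(coef(f)[1]), b = unname(coef(f)[2]))
    },
    exponential = fit_nls(x, y, function(a, b, x) a * exp(b * x),
                          init_exponential(x, y)),
    power = fit_nls(x, y, function(a, b, x) a * x^b,
                    init_power(x, y)))

  yhat <- family_predict(family, ab[["a"]], ab[["b"]], x)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  div <- if (rmse_divisor == "n") n else max(n - 2L, 1L)
  structure(list(family = family,
                 a = unname(ab[["a"]]), b = unname(ab[["b"]]),
                 r_squared = r2,
                 rmse = sqrt(ss_res / div),
                 n = n,
                 x_domain = range(x)),
            class = "ndvi_model")
}

# log-transform closed forms used to initialize the nonlinear fits
init_exponential <- function(x, y) {
  if (any(y <= 0)) return(c(a = mean(y), b = 0))
  f <- lm(log(y) ~ x)
  c(a = exp(unname(coef(f)[1])), b = unname(coef(f)[2]))
}

init_power <- function(x, y) {
  if (any(y <= 0)) return(c(a = mean(y), b = 0))
  f <- lm(log(y) ~ log(x))
  c(a = exp(unname(coef(f)[1])), b = unname(coef(f)[2]))
}

fit_nls <- function(x, y, fun, start) {
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fun(a, b, x),
                      start = list(a = start[["a"]], b = start[["b"]]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("nonlinear fit did not converge; returning the log-transform ",
            "initialisation instead", call. = FALSE)
    return(start)
  }
  cf <- coef(fit)
  c(a = unname(cf[["a"]]), b = unname(cf[["b"]]))
}

family_predict <- function(family, a, b, x) {
  switch(family,
         linear = a + b * x,
         exponential = a * exp(b * x),
         log = a + b * log(x),
         power = a * x^b)
}

#' @export
predict.ndvi_model <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else as.numeric(newdata)
  if (object$family %in% c("log", "power")) {
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad))
      stop_gt("family '%s' undefined at non-positive x: %s",
              object$family,
              paste(utils::head(x[bad], 5), collapse = ", "),
              class = "gt_domain_error")
  }
  family_predict(object$family, object$a, object$b, x)
}

#' @export
coef.ndvi_model <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
print.ndvi_model <- function(x, ...) {
  eqn <- switch(x$family,
                linear = sprintf("y = %.6g + %.6g x", x$a, x$b),
                exponential = sprintf("y = %.6g exp(%.6g x)", x$a, x$b),
                log = sprintf("y = %.6g + %.6g ln(x)", x$a, x$b),
                power = sprintf("y = %.6g x^%.6g", x$a, x$b))
  cat(sprintf("<%s regression>  %s\n", x$family, eqn))
  cat(sprintf("  n = %d, R2 = %.4f, RMSE = %.4g, x in [%.4g, %.4g]\n",
              x$n, x$r_squared, x$rmse, x$x_domain[1], x$x_domain[2]))
  invisible(x)
}

#' @export
summary.ndvi_model <- function(object, ...) {
  structure(object, class = c("summary.ndvi_model", class(object)))
}

#' @export
print.summary.ndvi_model <- function(x, ...) {
  print.ndvi_model(x, ...)
  cat(sprintf("  coefficients: a = %.8g, b = %.8g\n", x$a, x$b))
  invisible(x)
}

#' @export
plot.ndvi_model <- function(x, y, npoints = 200, ...) {
  xs <- seq(max(x$x_domain[1], if (x$family %in% c("log", "power"))
                                  .Machine$double.eps else -Inf),
            x$x_domain[2], length.out = npoints)
  graphics::plot(xs, predict(x, xs), type = "l",
                 xlab = "x", ylab = "fitted y",
                 main = sprintf("%s fit (R2 = %.3f)", x$family, x$r_squared),
                 ...)
  invisible(x)
}

#' Select the best regression among candidates
#'
#' Chooses the model with maximal R-squared; ties are broken by minimal
#' RMSE, then by the simplicity order linear < power < exponential < log.
#'
#' @param models a list of [fit_regression()] results fitted to the same
#'   data.
#' @return The winning `ndvi_model`.
#' @export
select_best <- function(models) {
  if (length(models) == 0L)
    stop_gt("no candidate models supplied", class = "gt_bad_arg")
  fam_order <- c(linear = 1, power = 2, exponential = 3, log = 4)
  r2 <- vapply(models, function(m) m$r_squared, 0)
  rmse <- vapply(models, function(m) m$rmse, 0)
  fam <- vapply(models, function(m) fam_order[[m$family]], 0)
  models[[order(-r2, rmse, fam)[1]]]
}

#' Fit all four families and keep the best
#'
#' Convenience wrapper: fits every family whose domain admits the data
#' (log/power are skipped when any `x <= 0`, exponential/power when a fit
#' fails outright) and returns [select_best()] over the candidates.
#'
#' @inheritParams fit_regression
#' @param families families to try.
#' @return The selected `ndvi_model`; the full candidate list is attached
#'   as attribute `"candidates"`.
#' @export
fit_best_regression <- function(x, y,
                                families = c("linear", "exponential",
                                             "log", "power")) {
  fits <- list()
  for (fam in families) {
    if (fam %in% c("log", "power") && any(x <= 0)) next
    m <- tryCatch(fit_regression(x, y, fam), error = function(e) NULL)
    if (!is.null(m)) fits[[fam]] <- m
  }
  if (length(fits) == 0L)
    stop_gt("no regression family could be fitted", class = "gt_fit_failure")
  best <- select_best(fits)
  attr(best, "candidates") <- fits
  best
}

#' Serialize / restore a regression model
#'
#' Models are portable JSON artifacts so a calibration fitted once can be
#' applied to any number of raster stacks.
#'
#' @param model an `ndvi_model`.
#' @param path file path to write to / read from.
#' @return `read_model()` returns the restored `ndvi_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  payload <- model[c("family", "a", "b", "r_squared", "rmse", "n")]
  payload$x_domain <- model$x_domain
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(family = p$family, a = p$a, b = p$b,
                 r_squared = p$r_squared, rmse = p$rmse,
                 n = as.integer(p$n), x_domain = as.numeric(p$x_domain)),
            class = "ndvi_model")
}
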