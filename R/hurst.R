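#' Mean rescaled range of a series at one window length
#'
#' Splits the series into `floor(n/tau)` consecutive non-overlapping
#' windows of length `tau` (trailing observations discarded). Each window
#' is demeaned; `R` is the range (max minus min) of the cumulative sums of
#' the deviations and `S` the window's population standard deviation
#' (divisor `tau`). The rescaled range `R/S` is averaged over windows with
#' `S > 0`; zero-variance windows are skipped.
#'
#' @param series numeric vector without NA.
#' @param tau window length, `2 <= tau <= length(series)`.
#' @return List of class `rs_point`: `tau`, `rs` (mean R/S), `n_windows`
#'   (windows actually used).
#' @examples
#' rescaled_range(c(1, 2), 2)$rs   # 1
#' @export
rescaled_range <- function(series, tau) {
  series <- as.numeric(series)
  n <- length(series)
  if (anyNA(series))
    stop_gt("series contains NA", class = "gt_bad_arg")
  if (tau < 2 || tau > n)
    stop_gt("tau = %d outside [2, %d]", tau, n, class = "gt_bad_arg")
  tau <- as.integer(tau)
  nw <- n %/% tau
  m <- matrix(series[seq_len(nw * tau)], nrow = tau)
  dev <- sweep(m, 2, colMeans(m))
  cs <- apply(dev, 2, cumsum)
  if (nw == 1L) cs <- matrix(cs, ncol = 1L)
  r <- apply(cs, 2, max) - apply(cs, 2, min)
  s <- sqrt(colMeans(dev^2))
  ok <- s > 0
  if (!any(ok))
    stop_gt("degenerate series: every window has zero variance at tau = %d",
            tau, class = "gt_degenerate_series")
  structure(list(tau = tau, rs = mean(r[ok] / s[ok]), n_windows = sum(ok)),
            class = "rs_point")
}

#' Default window-length grid for R/S analysis
#'
#' For short annual series (n <= 16, e.g. a 13-year record) the grid is
#' `{3, 4, 6, 12, 13}` intersected with `[2, n]`, giving varied window
#' counts from very few points. For longer series it is every integer from
#' 4 to `floor(n/2)` plus `n` itself.
#'
#' @param n series length.
#' @return Integer vector of window lengths.
#' @export
default_tau_grid <- function(n) {
  if (n <= 16L) {
    intersect(c(3L, 4L, 6L, 12L, 13L), seq(2L, n))
  } else {
    unique(c(4:(n %/% 2L), as.integer(n)))
  }
}

# Expected R/S of an i.i.d. Gaussian series (Anis-Lloyd, with the
# asymptotic gamma-ratio replacement above tau = 340); used by the
# optional small-sample bias correction.
expected_rs <- function(tau) {
  vapply(tau, function(t) {
    i <- seq_len(t - 1L)
    s <- sum(sqrt((t - i) / i))
    front <- if (t <= 340) {
      exp(lgamma((t - 1) / 2) - lgamma(t / 2)) / sqrt(pi)
    } else {
      1 / sqrt(t * pi / 2)
    }
    (t - 0.5) / t * front * s
  }, 0)
}

#' Hurst exponent by rescaled-range analysis
#'
#' Estimates the Hurst exponent H of a series by classical R/S analysis:
#' the mean rescaled range is computed for each window length in the
#' grid, and `log(R/S)` is regressed on `log(tau)` by ordinary least
#' squares; the fitted slope is H and the intercept `a` completes the
#' relation `log(R/S) = a + H * log(tau)`. H = 0.5 indicates a random
#' (memoryless) series, H > 0.5 a persistent one whose trend tends to
#' continue, H < 0.5 an anti-persistent one.
#'
#' The classical estimator is biased upward for short series; the
#' optional Anis-Lloyd correction (`anis_lloyd = TRUE`) regresses the
#' deviation of `log(R/S)` from its i.i.d. expectation instead, returning
#' `0.5 + slope`. The default is the uncorrected classical estimate.
#'
#' @param series numeric vector, length >= 8, no NA.
#' @param tau_grid integer window lengths (>= 3 distinct values in
#'   `[2, n]`); defaults to [default_tau_grid()].
#' @param anis_lloyd apply the small-sample bias correction?
#' @return List with `h`, `intercept`, and the `rs_points` table
#'   (`tau`, `rs`, `n_windows`).
#' @export
hurst_exponent <- function(series, tau_grid = NULL, anis_lloyd = FALSE) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 8L)
    stop_gt("series too short for R/S analysis (n = %d < 8)", n,
            class = "gt_bad_arg")
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(n)
  tau_grid <- sort(unique(as.integer(tau_grid)))
  tau_grid <- tau_grid[tau_grid >= 2L & tau_grid <= n]
  pts <- lapply(tau_grid, function(t)
    tryCatch(rescaled_range(series, t), error = function(e) NULL))
  keep <- !vapply(pts, is.null, TRUE)
  pts <- pts[keep]
  if (length(pts) < 3L)
    stop_gt("fewer than 3 valid R/S points; estimation failed",
            class = "gt_estimation_failed")
  tau <- vapply(pts, `[[`, 0, "tau")
  rs <- vapply(pts, `[[`, 0, "rs")
  lrs <- log(rs)
  lt <- log(tau)
  if (anis_lloyd) {
    fit <- lm(I(lrs - log(expected_rs(tau))) ~ lt)
    h <- 0.5 + unname(coef(fit)[2])
  } else {
    fit <- lm(lrs ~ lt)
    h <- unname(coef(fit)[2])
  }
  list(h = h, intercept = unname(coef(fit)[1]),
       rs_points = data.frame(tau = tau, rs = rs,
                              n_windows = vapply(pts, `[[`, 0, "n_windows")))
}

#' Sustainability class from a Hurst exponent
#'
#' `h > 0.5 + tol` means the observed trend is persistent (sustainable:
#' the future direction is expected to match the study period);
#' `h < 0.5 - tol` means anti-persistent (the trend tends to reverse);
#' values within the tolerance band, including exactly 0.5, are random.
#' The default `tol = 0` reproduces the strict `h > 0.5` rule.
#'
#' @param h numeric vector of Hurst exponents.
#' @param tol half-width of the "random" band around 0.5.
#' @return Factor with levels `sustainable`, `anti_sustainable`, `random`.
#' @export
classify_sustainability <- function(h, tol = 0) {
  check_number(tol, "tol", lower = 0)
  lv <- c("sustainable", "anti_sustainable", "random")
  cls <- rep(NA_character_, length(h))
  ok <- !is.na(h)
  cls[ok & h > 0.5 + tol] <- lv[1]
  cls[ok & h < 0.5 - tol] <- lv[2]
  cls[ok & abs(h - 0.5) <= tol] <- lv[3]
  factor(cls, levels = lv)
}

#' Per-pixel Hurst / sustainability map
#'
#' Runs [hurst_exponent()] and [classify_sustainability()] on every pixel
#' series of an annual stack. Pixels with any nodata year are nodata.
#'
#' @param stack annual [raster_stack()].
#' @param tau_grid window grid, default [default_tau_grid()] of the
#'   series length.
#' @param tol tolerance passed to [classify_sustainability()].
#' @param type_map optional type matrix (1 = meadow, 2 = steppe) to split
#'   the persistent-pixel fraction and mean H by grassland type.
#' @param anis_lloyd passed to [hurst_exponent()].
#' @return Object of class `hurst_result`: `h` and `intercept` matrices,
#'   `sustainability` factor matrix, `tau_grid`, `fraction_sustainable`
#'   (percent of valid pixels with h > 0.5), `mean_h`, and when a type
#'   map is given, `by_type` with the same quantities per type.
#' @export
hurst_map <- function(stack, tau_grid = NULL, tol = 0, type_map = NULL,
                      anis_lloyd = FALSE) {
  d <- dim(stack$values)
  n <- d[3]
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(n)
  y <- matrix(aperm(stack$values, c(3, 1, 2)), nrow = n)
  npix <- ncol(y)
  h <- rep(NA_real_, npix)
  a <- rep(NA_real_, npix)
  full <- colSums(is.na(y)) == 0L
  for (p in which(full)) {
    est <- tryCatch(hurst_exponent(y[, p], tau_grid, anis_lloyd),
                    error = function(e) NULL)
    if (!is.null(est)) { h[p] <- est$h; a[p] <- est$intercept }
  }
  cls <- classify_sustainability(h, tol)
  res <- list(h = matrix(h, d[1], d[2]),
              intercept = matrix(a, d[1], d[2]),
              sustainability = matrix(as.character(cls), d[1], d[2]),
              class_levels = levels(cls),
              tau_grid = tau_grid,
              fraction_sustainable = 100 * mean(h[!is.na(h)] > 0.5),
              mean_h = mean(h, na.rm = TRUE))
  if (!is.null(type_map)) {
    check_same_grid(stack, type_map, "stack and type map")
    tv <- as.vector(type_map)
    res$by_type <- lapply(c(meadow = 1L, steppe = 2L), function(code) {
      hh <- h[!is.na(h) & tv == code]
      list(fraction_sustainable = 100 * mean(hh > 0.5),
           mean_h = mean(hh), n_pixels = length(hh))
    })
  }
  structure(res, class = "hurst_result")
}

#' @export
print.hurst_result <- function(x, ...) {
  cat(sprintf("<hurst_result> %d x %d pixels, %d tau values\n",
              nrow(x$h), ncol(x$h), length(x$tau_grid)))
  cat(sprintf("  mean H = %.3f; %.2f%% of valid pixels persistent (H > 0.5)\n",
              x$mean_h, x$fraction_sustainable))
  if (!is.null(x$by_type))
    for (tp in names(x$by_type))
      cat(sprintf("  %s: mean H = %.3f, %.2f%% persistent (%d px)\n", tp,
                  x$by_type[[tp]]$mean_h,
                  x$by_type[[tp]]$fraction_sustainable,
                  x$by_type[[tp]]$n_pixels))
  invisible(x)
}
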