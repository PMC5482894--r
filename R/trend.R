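#' Per-pixel trend slope of an annual series
#'
#' Least-squares slope of a value series against the year index
#' `i = 1..n`, computed from the sum form
#' `(n * sum(i*y) - sum(i) * sum(y)) / (n * sum(i^2) - sum(i)^2)`,
#' which is algebraically the OLS slope `cov(i, y) / var(i)`. For annual
#' AGB stacks the units are kg/hm2 per year.
#'
#' @param series numeric vector, length >= 2, no NA.
#' @return The slope.
#' @examples
#' pixel_slope(5 + 2 * (1:13))   # 2
#' @export
pixel_slope <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2L)
    stop_gt("need >= 2 years, got %d", n, class = "gt_bad_arg")
  if (anyNA(series))
    stop_gt("series contains nodata; trend undefined under the strict policy",
            class = "gt_bad_arg")
  i <- seq_len(n)
  (n * sum(i * series) - sum(i) * sum(series)) /
    (n * sum(i^2) - sum(i)^2)
}

#' Classify a trend slope
#'
#' Maps slopes to the four-level scheme used for AGB change:
#' significant decrease (`slope < -threshold`), non-significant decrease
#' (`-threshold <= slope < 0`), non-significant increase
#' (`0 <= slope < threshold`), significant increase (`slope >=
#' threshold`). "Significant" here is a magnitude label on the slope
#' (default threshold 10 kg/hm2 per year), not a statistical test.
#'
#' @param slope numeric vector of finite slopes.
#' @param threshold positive magnitude threshold.
#' @return Factor with levels `sig_decrease`, `nonsig_decrease`,
#'   `nonsig_increase`, `sig_increase` (`NA` slopes stay `NA`).
#' @export
classify_trend <- function(slope, threshold = 10) {
  check_number(threshold, "threshold", lower = 0)
  lv <- c("sig_decrease", "nonsig_decrease", "nonsig_increase",
          "sig_increase")
  cls <- rep(NA_character_, length(slope))
  ok <- !is.na(slope)
  cls[ok & slope < -threshold] <- lv[1]
  cls[ok & slope >= -threshold & slope < 0] <- lv[2]
  cls[ok & slope >= 0 & slope < threshold] <- lv[3]
  cls[ok & slope >= threshold] <- lv[4]
  factor(cls, levels = lv)
}

#' Per-pixel trend map of an annual stack
#'
#' Computes the trend slope and its class at every pixel of an annual
#' stack, fully vectorized over pixels. Under the default `"strict"`
#' nodata policy a pixel with any missing year is nodata; under
#' `"pairwise"` the slope sums are recomputed over the available years
#' (with `n` adjusted), keeping pixels with >= 2 observations.
#'
#' @param stack annual [raster_stack()] with >= 2 layers.
#' @param threshold slope magnitude separating "significant" classes.
#' @param na_policy `"strict"` or `"pairwise"`.
#' @return Object of class `trend_result`: `slope` matrix, `trend_class`
#'   factor matrix, `n_years`, `threshold`, and `class_fractions`
#'   (percent of non-nodata pixels per class).
#' @export
trend_map <- function(stack, threshold = 10,
                      na_policy = c("strict", "pairwise")) {
  na_policy <- match.arg(na_policy)
  d <- dim(stack$values)
  n <- d[3]
  if (n < 2L)
    stop_gt("trend needs >= 2 annual layers, got %d", n,
            class = "gt_bad_arg")
  y <- matrix(aperm(stack$values, c(3, 1, 2)), nrow = n)  # years x pixels
  i <- seq_len(n)
  if (na_policy == "strict") {
    slope <- rep(NA_real_, ncol(y))
    full <- colSums(is.na(y)) == 0L
    if (any(full)) {
      yy <- y[, full, drop = FALSE]
      slope[full] <- (n * colSums(i * yy) - sum(i) * colSums(yy)) /
        (n * sum(i^2) - sum(i)^2)
    }
  } else {
    obs <- !is.na(y)
    y0 <- ifelse(obs, y, 0)
    m <- colSums(obs)
    si <- colSums(i * obs)
    si2 <- colSums(i^2 * obs)
    sy <- colSums(y0)
    siy <- colSums(i * y0)
    den <- m * si2 - si^2
    slope <- ifelse(m >= 2 & den > 0, (m * siy - si * sy) / den, NA_real_)
  }
  slope_m <- matrix(slope, d[1], d[2])
  cls <- classify_trend(slope, threshold)
  frac <- prop.table(table(cls)) * 100
  structure(list(slope = slope_m,
                 trend_class = matrix(as.character(cls), d[1], d[2]),
                 class_levels = levels(cls),
                 n_years = n,
                 threshold = threshold,
                 class_fractions = frac),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %d x %d pixels, %d years, threshold %g\n",
              nrow(x$slope), ncol(x$slope), x$n_years, x$threshold))
  cat("  class fractions (% of valid pixels):\n")
  print(round(x$class_fractions, 2))
  invisible(x)
}

#' @export
summary.trend_result <- function(object, ...) {
  s <- object$slope[!is.na(object$slope)]
  cat(sprintf("slopes: mean %.3f, sd %.3f, range [%.3f, %.3f]; %d valid pixels\n",
              mean(s), sd(s), min(s), max(s), length(s)))
  print(object)
  invisible(object)
}
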