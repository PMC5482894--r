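#' Georeferenced raster stack
#'
#' The container used for all gridded data in the pipeline: a
#' `nrow x ncol x ntime` numeric array plus time labels and a simple
#' affine georeference. `NA` cells are nodata. Row 1 is the northern edge;
#' cell (1, 1) is the north-west corner.
#'
#' @param values numeric array `c(nrow, ncol, ntime)`, or a matrix for a
#'   single-layer stack. `NA` encodes nodata.
#' @param times numeric time labels, strictly increasing: integer years for
#'   annual stacks, or `year + (period - 1)/n_periods` for within-year
#'   composites (e.g. 16-day steps).
#' @param transform affine georeference `c(xmin, ymax, xres, yres)`: the
#'   outer corner of cell (1, 1) and the cell size in map units.
#' @param variable `"ndvi"` or `"agb"`; NDVI stacks are validated to lie
#'   in \[-1, 1\] where not nodata.
#' @return An object of class `raster_stack`.
#' @examples
#' v <- array(runif(4 * 5 * 3), c(4, 5, 3))
#' st <- raster_stack(v, times = 2000:2002, variable = "ndvi")
#' dim(st)
#' @export
raster_stack <- function(values, times,
                         transform = c(xmin = 0, ymax = 0, xres = 1, yres = 1),
                         variable = c("ndvi", "agb")) {
  variable <- match.arg(variable)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_gt("values must be a matrix or 3-D array", class = "gt_bad_raster")
  times <- as.numeric(times)
  if (length(times) != dim(values)[3])
    stop_gt("length(times) = %d does not match %d layers",
            length(times), dim(values)[3], class = "gt_bad_raster")
  if (is.unsorted(times, strictly = TRUE))
    stop_gt("times must be strictly increasing", class = "gt_bad_raster")
  if (variable == "ndvi") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1 || max(v) > 1))
      stop_gt("NDVI values outside [-1, 1]", class = "gt_bad_raster")
  }
  structure(list(values = values, times = times,
                 transform = as.numeric(transform), variable = variable),
            class = "raster_stack")
}

#' @export
dim.raster_stack <- function(x) dim(x$values)

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_stack: %s> %d x %d cells, %d layer(s)\n",
              x$variable, d[1], d[2], d[3]))
  cat(sprintf("  times: %s%s\n",
              paste(utils::head(x$times, 6), collapse = ", "),
              if (d[3] > 6) ", ..." else ""))
  cat(sprintf("  nodata cells: %d of %d\n",
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

n_layers <- function(stack) dim(stack$values)[3]

check_same_grid <- function(a, b, what = "rasters") {
  da <- dim(a)[1:2]
  db <- if (inherits(b, "raster_stack")) dim(b)[1:2] else dim(b)
  if (!identical(da, db))
    stop_gt("%s are on different grids (%dx%d vs %dx%d)",
            what, da[1], da[2], db[1], db[2], class = "gt_grid_mismatch")
  invisible(TRUE)
}

#' Annual maximum value composite
#'
#' Per pixel and year, takes the maximum NDVI/AGB over the year's
#' non-nodata layers (maximum value compositing, the standard way to build
#' annual vegetation-index layers while suppressing cloud and atmosphere
#' artifacts). Pixels with no valid observation in a year become nodata.
#' Applying it to an already-annual stack returns the stack unchanged.
#'
#' @param stack a [raster_stack()]; `floor(times)` gives each layer's year.
#' @return A `raster_stack` with one layer per year, times = the years.
#' @export
annual_mvc <- function(stack) {
  if (n_layers(stack) == 0L)
    stop_gt("empty stack", class = "gt_bad_raster")
  years <- floor(stack$times)
  uy <- sort(unique(years))
  d <- dim(stack$values)
  out <- array(NA_real_, c(d[1], d[2], length(uy)))
  for (k in seq_along(uy)) {
    sel <- which(years == uy[k])
    sub <- stack$values[, , sel, drop = FALSE]
    m <- apply(sub, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    out[, , k] <- m
  }
  raster_stack(out, uy, stack$transform, stack$variable)
}

#' Block aggregation to a coarser grid
#'
#' Aggregates each layer by `factor x factor` blocks (e.g. factor 10 turns
#' a 1 km grid into a 10 km grid). Each output cell is the chosen statistic
#' of the block's non-nodata cells; all-nodata blocks stay nodata. Edge
#' blocks that the factor does not divide use the cells available.
#'
#' @param stack a [raster_stack()].
#' @param factor positive integer block size.
#' @param stat `"mean"` (default), `"max"` or `"median"`.
#' @return A `raster_stack` on the coarser grid with rescaled transform.
#' @export
aggregate_raster <- function(stack, factor, stat = c("mean", "max", "median")) {
  stat <- match.arg(stat)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop_gt("factor must be a positive integer", class = "gt_bad_arg")
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)
  f <- switch(stat, mean = mean, max = max, median = stats::median)
  d <- dim(stack$values)
  nr <- ceiling(d[1] / factor)
  nc <- ceiling(d[2] / factor)
  ri <- ((seq_len(d[1]) - 1L) %/% factor) + 1L
  ci <- ((seq_len(d[2]) - 1L) %/% factor) + 1L
  out <- array(NA_real_, c(nr, nc, d[3]))
  for (t in seq_len(d[3])) {
    layer <- stack$values[, , t]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      block <- layer[ri == i, ci == j]
      block <- block[!is.na(block)]
      if (length(block)) out[i, j, t] <- f(block)
    }
  }
  tr <- stack$transform
  raster_stack(out, stack$times,
               c(tr[1], tr[2], tr[3] * factor, tr[4] * factor),
               stack$variable)
}

#' Write / read a raster stack as plain text
#'
#' Serializes a stack to a pair of files: `<path>.csv` with one row per
#' cell-time (columns `time`, `row`, `col`, `value`; nodata cells written
#' with empty value) and `<path>.json` holding the grid shape, transform
#' and variable. The format is lossless and diff-able.
#'
#' @param stack a [raster_stack()].
#' @param path base path without extension.
#' @return `read_stack()` returns the restored stack; `write_stack()`
#'   returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$values)
  df <- data.frame(
    time = rep(stack$times, each = d[1] * d[2]),
    row = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    value = as.vector(stack$values))
  write.csv(df, paste0(path, ".csv"), row.names = FALSE, na = "")
  jsonlite::write_json(
    list(nrow = d[1], ncol = d[2], ntime = d[3], times = stack$times,
         transform = stack$transform, variable = stack$variable),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(path, ".csv"))
  v <- array(NA_real_, c(hdr$nrow, hdr$ncol, hdr$ntime))
  ti <- match(df$time, hdr$times)
  v[cbind(df$row, df$col, ti)] <- df$value
  raster_stack(v, hdr$times, hdr$transform, hdr$variable)
}
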