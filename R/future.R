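#' Combine trend and sustainability classes
#'
#' A sustainable pixel keeps its trend class (the observed direction is
#' expected to continue), giving the four `s_*` classes; an
#' anti-persistent pixel's future is uncertain regardless of its trend;
#' a random pixel (H exactly at 0.5) gets its own uncertain class, which
#' `paper_mode = TRUE` collapses into the anti-sustainable one so the six
#' classes reduce to the five mapped in practice.
#'
#' @param trend_class factor/character vector with levels as in
#'   [classify_trend()].
#' @param sustainability factor/character vector with levels as in
#'   [classify_sustainability()].
#' @param paper_mode collapse `random_uncertain` into
#'   `anti_sustainable_uncertain`?
#' @return Factor with levels `s_sig_decrease`, `s_nonsig_decrease`,
#'   `s_nonsig_increase`, `s_sig_increase`, `anti_sustainable_uncertain`,
#'   `random_uncertain`. NA in either input gives NA.
#' @export
combine_future <- function(trend_class, sustainability, paper_mode = FALSE) {
  tc <- as.character(trend_class)
  sc <- as.character(sustainability)
  if (length(tc) != length(sc))
    stop_gt("trend and sustainability inputs differ in length",
            class = "gt_bad_arg")
  lv <- c("s_sig_decrease", "s_nonsig_decrease", "s_nonsig_increase",
          "s_sig_increase", "anti_sustainable_uncertain", "random_uncertain")
  out <- rep(NA_character_, length(tc))
  ok <- !is.na(tc) & !is.na(sc)
  sus <- ok & sc == "sustainable"
  out[sus] <- paste0("s_", tc[sus])
  out[ok & sc == "anti_sustainable"] <- "anti_sustainable_uncertain"
  out[ok & sc == "random"] <-
    if (paper_mode) "anti_sustainable_uncertain" else "random_uncertain"
  bad <- ok & is.na(match(out, lv)) & !is.na(out)
  if (any(bad))
    stop_gt("unrecognised trend class: %s", unique(tc[bad])[1],
            class = "gt_bad_arg")
  factor(out, levels = lv)
}

#' Area fractions of the future-dynamics classes
#'
#' Percentage of non-nodata grassland pixels in each future class,
#' overall and split by grassland type, with two aggregates mirroring the
#' usual reading of the map: `improvement` (sustainable increase classes)
#' and `degradation` (sustainable decrease classes).
#'
#' @param class_map factor/character matrix from [combine_future()].
#' @param type_map integer matrix, 1 = meadow, 2 = steppe,
#'   0/NA = non-grassland, same grid.
#' @return Data frame with columns `class`, `overall_pct`, `meadow_pct`,
#'   `steppe_pct`; the last two rows are the aggregates.
#' @export
area_fractions <- function(class_map, type_map = NULL) {
  cls <- as.character(class_map)
  lv <- c("s_sig_decrease", "s_nonsig_decrease", "s_nonsig_increase",
          "s_sig_increase", "anti_sustainable_uncertain", "random_uncertain")
  if (is.null(type_map)) {
    tv <- rep(1L, length(cls))
  } else {
    if (length(type_map) != length(cls))
      stop_gt("class map and type map are on different grids",
              class = "gt_grid_mismatch")
    tv <- as.integer(as.vector(type_map))
  }
  pct <- function(sel) {
    valid <- sel & !is.na(cls)
    tot <- sum(valid)
    if (tot == 0) return(setNames(rep(NA_real_, length(lv)), lv))
    100 * vapply(lv, function(l) sum(cls[valid] == l), 0) / tot
  }
  overall <- pct(!is.na(tv) & tv %in% c(1L, 2L))
  meadow <- pct(!is.na(tv) & tv == 1L)
  steppe <- pct(!is.na(tv) & tv == 2L)
  out <- data.frame(class = lv, overall_pct = unname(overall),
                    meadow_pct = unname(meadow),
                    steppe_pct = unname(steppe))
  agg <- function(v, cols) sum(v[match(cols, lv)])
  up <- c("s_nonsig_increase", "s_sig_increase")
  down <- c("s_nonsig_decrease", "s_sig_decrease")
  rbind(out,
        data.frame(class = "improvement",
                   overall_pct = agg(overall, up),
                   meadow_pct = agg(meadow, up),
                   steppe_pct = agg(steppe, up)),
        data.frame(class = "degradation",
                   overall_pct = agg(overall, down),
                   meadow_pct = agg(meadow, down),
                   steppe_pct = agg(steppe, down)))
}

#' Future-dynamics map from trend and Hurst results
#'
#' Convenience wrapper combining a [trend_map()] and a [hurst_map()]
#' result into the per-pixel future classification plus its area-fraction
#' table.
#'
#' @param trend a `trend_result`.
#' @param hurst a `hurst_result` on the same grid.
#' @param type_map optional type matrix for per-type fractions.
#' @param paper_mode passed to [combine_future()].
#' @return Object of class `future_result`: `classes` (factor matrix) and
#'   `fractions` (data frame).
#' @export
future_map <- function(trend, hurst, type_map = NULL, paper_mode = FALSE) {
  if (!identical(dim(trend$slope), dim(hurst$h)))
    stop_gt("trend and Hurst maps are on different grids",
            class = "gt_grid_mismatch")
  cls <- combine_future(trend$trend_class, hurst$sustainability, paper_mode)
  structure(list(classes = matrix(as.character(cls),
                                  nrow(trend$slope), ncol(trend$slope)),
                 class_levels = levels(cls),
                 fractions = area_fractions(cls, type_map)),
            class = "future_result")
}

#' @export
print.future_result <- function(x, ...) {
  cat(sprintf("<future_result> %d x %d pixels\n",
              nrow(x$classes), ncol(x$classes)))
  print(transform(x$fractions,
                  overall_pct = round(overall_pct, 2),
                  meadow_pct = round(meadow_pct, 2),
                  steppe_pct = round(steppe_pct, 2)))
  invisible(x)
}
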