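# Summary metrics: N budgets, NUE, percent reductions, quality mapping,
# prediction-ratio statistics, NDRE-clipping correlation.

#' Clipping-to-quality mapping
#'
#' Piecewise-linear map from daily clipping yield (g m-2 d-1) to visual
#' turfgrass quality on the 1-9 scale, anchored at (1.25, 6) and (1.6, 7) --
#' the observed band where quality sits between minimally acceptable (6) and
#' good (7). Below the lowest anchor the map descends linearly to the
#' natural endpoint (0 clipping, quality 1): zero growth is completely dead
#' turf. Above the highest anchor the anchor-segment slope is extended.
#' Results are clipped to [1, 9].
#'
#' @param anchors two-column matrix or data.frame of (clipping, quality)
#'   anchor points; default `rbind(c(1.25, 6), c(1.6, 7))`.
#' @return An object of class `quality_map`.
#' @export
quality_map <- function(anchors = rbind(c(1.25, 6), c(1.6, 7))) {
  a <- as.matrix(anchors)
  if (ncol(a) != 2 || nrow(a) < 2) stop("need >= 2 (clipping, quality) anchors", call. = FALSE)
  a <- a[order(a[, 1]), , drop = FALSE]
  if (any(diff(a[, 1]) <= 0) || any(diff(a[, 2]) <= 0))
    stop("anchors must be strictly increasing in both coordinates", call. = FALSE)
  if (a[1, 1] <= 0 || a[1, 2] <= 1)
    stop("anchors must lie above the (0 clipping, quality 1) endpoint", call. = FALSE)
  structure(list(anchors = a, floor = 1, ceiling = 9), class = "quality_map")
}

#' Visual quality from daily clipping yield
#'
#' @param daily_yield daily clipping yield, g m-2 d-1 (vectorized, >= 0).
#' @param map a [quality_map()].
#' @return Quality scores in [1, 9].
#' @examples
#' quality_from_clipping(c(1.25, 1.425, 1.6)) # 6, 6.5, 7
#' @export
quality_from_clipping <- function(daily_yield, map = quality_map()) {
  stopifnot(inherits(map, "quality_map"))
  if (any(!is.finite(daily_yield)) || any(daily_yield < 0))
    stop("`daily_yield` must be finite and non-negative", call. = FALSE)
  a <- map$anchors
  # interpolate through (0, floor) and the anchors; extend the top anchor
  # segment's slope above it, then clip to the scale
  x <- c(0, a[, 1]); y <- c(map$floor, a[, 2])
  n <- length(x)
  q <- stats::approx(x, y, xout = daily_yield, rule = 2)$y
  hi <- daily_yield > x[n]
  s_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  q[hi] <- y[n] + s_hi * (daily_yield[hi] - x[n])
  pmin(map$ceiling, pmax(map$floor, q))
}

# Inverse of the anchor segment: clipping rate at a given quality (used for
# NDRE calibration). Only valid between the outer anchor qualities extended
# by the edge slopes.
clipping_at_quality <- function(map, quality) {
  a <- map$anchors
  x <- a[, 1]; y <- a[, 2]
  n <- nrow(a)
  if (quality <= y[1]) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    return(x[1] + (quality - y[1]) / s)
  }
  if (quality >= y[n]) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    return(x[n] + (quality - y[n]) / s)
  }
  stats::approx(y, x, xout = quality)$y
}

#' Nitrogen budget and nitrogen use efficiency for one plot
#'
#' Uptake is clipping mass times tissue N concentration, converted to
#' kg ha-1. NUE subtracts the uptake of an unfertilized control plot over
#' the same period and divides by the fertilizer applied:
#' `NUE = (uptake - control_clipping * tissue_n * 10) / cum_n_applied * 100`.
#'
#' @param cum_clipping cumulative clipping mass of the fertilized plot,
#'   g m-2 over the accounting period.
#' @param cum_n_applied cumulative fertilizer N, kg ha-1 over the period.
#' @param control_clipping cumulative clipping of a zero-N control plot on
#'   the same root zone and period, g m-2.
#' @param ncp [nitrogen_cycle_params()].
#' @return An object of class `n_budget_summary` with fields
#'   `cum_n_applied`, `cum_clipping`, `uptake` (kg ha-1) and `nue` (%,
#'   `NA` for an unfertilized plot, where NUE is undefined).
#' @examples
#' n_budget(184.2, 80, 64.9)$nue # 58.2% from the printed two-year totals
#' @export
n_budget <- function(cum_clipping, cum_n_applied, control_clipping,
                     ncp = nitrogen_cycle_params()) {
  stop_if_not_number(cum_clipping, "cum_clipping", lower = 0)
  stop_if_not_number(cum_n_applied, "cum_n_applied", lower = 0)
  stop_if_not_number(control_clipping, "control_clipping", lower = 0)
  k <- ncp$tissue_n_fraction * ncp$area_mass_conversion
  uptake <- cum_clipping * k
  nue <- if (cum_n_applied > 0) {
    (uptake - control_clipping * k) / cum_n_applied * 100
  } else NA_real_
  structure(list(cum_n_applied = cum_n_applied,
                 cum_clipping = cum_clipping,
                 uptake = uptake,
                 nue = nue),
            class = "n_budget_summary")
}

#' @export
print.n_budget_summary <- function(x, ...) {
  cat(sprintf("N budget: applied %.1f kg ha-1 | clipping %.1f g m-2 | uptake %.1f kg ha-1 | NUE %s\n",
              x$cum_n_applied, x$cum_clipping, x$uptake,
              if (is.na(x$nue)) "undefined (control)" else sprintf("%.1f%%", x$nue)))
  invisible(x)
}

#' Percent reduction in fertilizer use relative to a reference strategy
#'
#' `(reference - other) / reference * 100`, rounded to the nearest integer
#' with halves away from zero (matching hand-rounded report tables).
#'
#' @param reference_total reference cumulative N, kg ha-1 (> 0).
#' @param other_total compared cumulative N, kg ha-1.
#' @param digits rounding digits (default 0); use `NULL` for no rounding.
#' @return Percent reduction.
#' @examples
#' percent_reduction(281, 190) # 32
#' percent_reduction(281, 80)  # 72
#' @export
percent_reduction <- function(reference_total, other_total, digits = 0) {
  stop_if_not_number(reference_total, "reference_total")
  if (reference_total <= 0)
    stop("`reference_total` must be positive", call. = FALSE)
  p <- (reference_total - other_total) / reference_total * 100
  if (is.null(digits)) p else round_half_up(p, digits)
}

#' Five-number summary of predicted/observed yield ratios
#'
#' For each aligned interval the ratio `predicted / observed` is formed; the
#' summary reports min, lower quartile, median, upper quartile and max (the
#' statistics a ratio box plot displays), plus the ratio vector itself.
#'
#' @param predicted,observed aligned per-interval cumulative clipping yields
#'   (g m-2 per interval); `observed` must be positive.
#' @return An object of class `ratio_stats`.
#' @export
ratio_stats <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  if (length(observed) == 0) stop("no intervals supplied", call. = FALSE)
  if (any(observed <= 0))
    stop("`observed` must be strictly positive to form ratios", call. = FALSE)
  r <- predicted / observed
  q <- stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  structure(list(ratios = r, min = q[1], q25 = q[2], median = q[3],
                 q75 = q[4], max = q[5]),
            class = "ratio_stats")
}

#' @export
print.ratio_stats <- function(x, ...) {
  cat(sprintf("predicted/observed ratios (n = %d): min %.2f | q25 %.2f | median %.2f | q75 %.2f | max %.2f\n",
              length(x$ratios), x$min, x$q25, x$median, x$q75, x$max))
  invisible(x)
}

#' Pearson correlation between NDRE and clipping yield
#'
#' Product-moment correlation between paired daily NDRE readings and
#' clipping yields, with the usual t-test p-value.
#'
#' @param ndre,clipping paired observations (length >= 3, both with nonzero
#'   variance).
#' @return A list with `r`, `p_value`, `n`.
#' @export
ndre_clipping_correlation <- function(ndre, clipping) {
  if (length(ndre) != length(clipping))
    stop("`ndre` and `clipping` must have equal length", call. = FALSE)
  ok <- is.finite(ndre) & is.finite(clipping)
  ndre <- ndre[ok]; clipping <- clipping[ok]
  if (length(ndre) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(ndre) == 0 || stats::sd(clipping) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(ndre)))
  ct <- stats::cor.test(ndre, clipping, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(ndre))
}
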