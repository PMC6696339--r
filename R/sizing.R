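# Size-vs-metric curves: interpolating cubic splines through the ladder
# knots, dense integer grids, threshold crossings and curve peaks.

#' Fit a cubic-spline size-diversity curve
#'
#' Interpolating (natural, by default) cubic spline through the
#' (library size, metric value) knots, evaluated on the dense integer grid
#' from the smallest to the largest knot at step 1. For the 100 to 100,000
#' knot range this grid has exactly 99,901 points. Extrapolation beyond the
#' knot range is deliberately not offered.
#'
#' @param sizes strictly ascending knot sizes (at least 3).
#' @param values metric values at the knots.
#' @param bc spline boundary condition: `"natural"` (zero second
#'   derivative, default) or `"fmm"` (Forsythe-Malcolm-Moler end cubics).
#' @return An object of class `size_curve`: list with `knots` (data.frame
#'   `size`, `value`), `interpolant` (function), and `grid` (data.frame
#'   `size`, `value` over the step-1 grid).
#' @export
fit_curve <- function(sizes, values, bc = c("natural", "fmm")) {
  bc <- match.arg(bc)
  sizes <- as.numeric(sizes)
  if (length(sizes) < 3L) stop("need at least 3 knots")
  if (length(values) != length(sizes)) stop("sizes and values differ in length")
  if (anyDuplicated(sizes)) stop("duplicate knot sizes")
  if (is.unsorted(sizes, strictly = TRUE)) stop("knot sizes must be ascending")
  f <- stats::splinefun(sizes, values, method = bc)
  grid_sizes <- seq(min(sizes), max(sizes), by = 1)
  structure(list(knots = data.frame(size = sizes, value = values),
                 interpolant = f,
                 grid = data.frame(size = grid_sizes,
                                   value = f(grid_sizes))),
            class = "size_curve")
}

#' @export
print.size_curve <- function(x, ...) {
  cat(sprintf("size_curve: %d knot(s) on [%g, %g], grid of %d point(s)\n",
              nrow(x$knots), min(x$knots$size), max(x$knots$size),
              nrow(x$grid)))
  invisible(x)
}

#' Minimum library size achieving a metric threshold
#'
#' The smallest grid size whose interpolated metric value is at least
#' `threshold`. When a pool total is supplied, the size is also reported as
#' a ratio of the pool.
#'
#' @param curve a [fit_curve()] result.
#' @param threshold metric value to reach.
#' @param pool_total optional total pool size for the ratio.
#' @param metric optional metric name carried through to the result.
#' @return An object of class `size_estimate`: list with `threshold`,
#'   `metric`, `attained` (logical), `minimum_size` (NA when not attained),
#'   and `ratio` (NA without `pool_total`).
#' @export
min_size_for <- function(curve, threshold, pool_total = NULL, metric = NA) {
  stopifnot(inherits(curve, "size_curve"))
  hit <- which(curve$grid$value >= threshold)
  attained <- length(hit) > 0L
  size <- if (attained) curve$grid$size[hit[1]] else NA_real_
  structure(list(threshold = threshold, metric = metric, attained = attained,
                 minimum_size = size,
                 ratio = if (!is.null(pool_total) && attained)
                   size / pool_total else NA_real_),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  if (x$attained)
    cat(sprintf("size_estimate: threshold %g reached at size %g%s\n",
                x$threshold, x$minimum_size,
                if (!is.na(x$ratio)) sprintf(" (%.2f%% of pool)",
                                             100 * x$ratio) else ""))
  else
    cat(sprintf("size_estimate: threshold %g not attained on the grid\n",
                x$threshold))
  invisible(x)
}

#' Peak of a size-diversity curve
#'
#' Grid point with the maximal interpolated value (first such point on
#' ties); for monotone increasing curves this is the last grid point.
#'
#' @param curve a [fit_curve()] result.
#' @return list with `size` and `value`.
#' @export
peak_size <- function(curve) {
  stopifnot(inherits(curve, "size_curve"))
  i <- which.max(curve$grid$value)
  list(size = curve$grid$size[i], value = curve$grid$value[i])
}

#' Coverage thresholds for minimum-size estimation
#'
#' Builds the standard threshold set: fractions of the pool's total richness
#' (by default 5% and 10%) plus the pool-level overall true diversity.
#'
#' @param total_richness richness of the whole pool.
#' @param overall_D true diversity of the whole pool.
#' @param fractions richness fractions in (0, 1].
#' @return data.frame with columns `name`, `metric`, `value`.
#' @export
coverage_targets <- function(total_richness, overall_D,
                             fractions = c(0.05, 0.10)) {
  stopifnot(total_richness >= 1, all(fractions > 0 & fractions <= 1))
  data.frame(
    name = c(sprintf("%g%% total richness", 100 * fractions),
             "Overall true diversity"),
    metric = c(rep("richness", length(fractions)), "true_diversity"),
    value = c(fractions * total_richness, overall_D),
    stringsAsFactors = FALSE)
}

#' Minimum-size coverage table for a pool
#'
#' Combines richness and true-diversity size curves with pool-level totals
#' into the standard coverage report: minimum sizes (and pool ratios) for
#' 5%/10% richness coverage, for the pool's overall true diversity, and for
#' the maximum of the true-diversity curve.
#'
#' @param richness_curve,diversity_curve [fit_curve()] results for richness
#'   and true diversity against library size.
#' @param total_richness,overall_D pool-level richness and true diversity.
#' @param pool_total pool size for the ratios.
#' @param fractions richness coverage fractions.
#' @return data.frame with columns `threshold_name`, `threshold_value`,
#'   `minimum_size`, `ratio_of_pool`.
#' @export
coverage_table <- function(richness_curve, diversity_curve, total_richness,
                           overall_D, pool_total,
                           fractions = c(0.05, 0.10)) {
  targets <- coverage_targets(total_richness, overall_D, fractions)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    curve <- if (targets$metric[i] == "richness") richness_curve
             else diversity_curve
    est <- min_size_for(curve, targets$value[i], pool_total,
                        metric = targets$metric[i])
    data.frame(threshold_name = targets$name[i],
               threshold_value = targets$value[i],
               minimum_size = est$minimum_size,
               ratio_of_pool = est$ratio, stringsAsFactors = FALSE)
  })
  pk <- peak_size(diversity_curve)
  rows <- c(rows, list(data.frame(
    threshold_name = "Maximum true diversity",
    threshold_value = pk$value, minimum_size = pk$size,
    ratio_of_pool = pk$size / pool_total, stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}
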