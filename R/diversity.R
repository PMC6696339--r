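# Library-level diversity metrics: mean nearest-neighbor Tanimoto
# similarity, richness, true diversity, and marginal series over a size
# ladder.

#' Mean nearest-neighbor Tanimoto similarity
#'
#' For every compound, the maximum Tanimoto similarity to any other library
#' member (self-comparison excluded); the metric is the arithmetic mean of
#' these per-compound maxima. Computed by brute force over all pairs, so the
#' value is exact.
#'
#' @param fps list of at least two fingerprint sets.
#' @return value in `[0, 1]`.
#' @export
mean_nn_similarity <- function(fps) {
  if (length(fps) < 2L)
    stop("mean_nn_similarity needs a library of size >= 2")
  ix <- .fp_index(fps)
  mean(cpp_nn_max_sim(ix$sets))
}

#' Richness of a library
#'
#' The number of distinct fingerprint features present.
#'
#' @param ab a [pooled_abundance()] table.
#' @return integer `R >= 1`.
#' @export
richness <- function(ab) {
  if (length(ab) == 0L) stop("empty abundance table")
  length(ab)
}

#' True diversity of a library
#'
#' The effective number of equally-common structural features,
#' `D = 1 / prod(p_i^p_i)` with `p_i = n_i / total`, computed in log space
#' as `exp(-sum(p_i * log(p_i)))` (the exponential of Shannon entropy) to
#' avoid underflow at large richness. `1 <= D <= R`, with `D = R` exactly
#' when all abundances are equal.
#'
#' @param ab a [pooled_abundance()] table (any named positive count vector).
#' @return `D`, a positive number.
#' @export
true_diversity <- function(ab) {
  if (length(ab) == 0L) stop("empty abundance table")
  counts <- as.numeric(ab)
  if (any(counts <= 0)) stop("abundance counts must be positive")
  p <- counts / sum(counts)
  exp(-sum(p * log(p)))
}

#' Marginal (per-added-compound) metric series
#'
#' Interval slopes of a metric across a size ladder:
#' `(value[k+1] - value[k]) / (size[k+1] - size[k])`. Prepend the origin
#' `(0, 0)` to the inputs when the first marginal should read "metric per
#' compound from nothing".
#'
#' @param sizes strictly ascending integer library sizes.
#' @param values metric values at each size.
#' @return An object of class `marginal_series`: list with `sizes`,
#'   `values`, and `marginals` (one per interval).
#' @export
marginal_series <- function(sizes, values) {
  if (length(sizes) != length(values) || length(sizes) < 2L)
    stop("need equally many sizes and values, at least 2")
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly ascending")
  structure(list(sizes = sizes, values = values,
                 marginals = diff(values) / diff(sizes)),
            class = "marginal_series")
}

#' @export
print.marginal_series <- function(x, ...) {
  df <- data.frame(from = x$sizes[-length(x$sizes)], to = x$sizes[-1],
                   marginal = x$marginals)
  print(df)
  invisible(x)
}

# Metrics for one library given as a fingerprint list.
.library_report <- function(fps) {
  ab <- pooled_abundance(fps)
  data.frame(size = length(fps),
             mean_nn_similarity = mean_nn_similarity(fps),
             richness = richness(ab),
             true_diversity = true_diversity(ab))
}

#' Evaluate the three diversity metrics along a size ladder
#'
#' Takes nested prefix libraries (see [nested_prefixes()]) and returns one
#' row of metrics per ladder size. When several replicate ladders are given
#' (the random-selection triplicate control), per-replicate rows are
#' averaged size-wise; the raw per-replicate table is attached as attribute
#' `replicates` so error bars remain available.
#'
#' @param fps a [radial_fingerprints()] result covering the pool.
#' @param selections a single `selection_result` or a list of replicate
#'   `selection_result`s.
#' @param sizes ascending ladder sizes (each `>= 2`).
#' @return data.frame with columns `size`, `mean_nn_similarity`,
#'   `richness`, `true_diversity`, `method`, `seed` (NA when averaged over
#'   replicates or for sphere exclusion).
#' @export
evaluate_ladder <- function(fps, selections, sizes) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  sizes <- as.integer(sizes)
  if (any(sizes < 2L)) stop("every ladder size must be >= 2")

  per_rep <- lapply(selections, function(res) {
    prefixes <- nested_prefixes(res, sizes)
    rows <- do.call(rbind, lapply(prefixes, function(ids)
      .library_report(fps[ids])))
    rows$method <- res$method
    rows$seed <- if (is.null(res$seed)) NA_integer_ else res$seed
    rows
  })
  reps <- do.call(rbind, per_rep)
  rownames(reps) <- NULL

  if (length(selections) == 1L) {
    attr(reps, "replicates") <- reps
    return(reps)
  }
  avg <- do.call(rbind, lapply(split(reps, reps$size), function(d)
    data.frame(size = d$size[1],
               mean_nn_similarity = mean(d$mean_nn_similarity),
               richness = mean(d$richness),
               true_diversity = mean(d$true_diversity),
               method = d$method[1], seed = NA_integer_)))
  avg <- avg[order(avg$size), , drop = FALSE]
  rownames(avg) <- NULL
  attr(avg, "replicates") <- reps
  avg
}
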