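# Diverse sub-library selection: directed sphere exclusion on Tanimoto
# distance, and seeded uniform random selection as the control.

.new_selection_result <- function(method, ordered_ids, source_size,
                                  exclusion_radius = NULL, seed = NULL,
                                  ordering = NULL) {
  structure(list(method = method, ordered_ids = ordered_ids,
                 exclusion_radius = exclusion_radius, seed = seed,
                 ordering = ordering, source_size = source_size),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d of %d compound(s)", x$method,
              length(x$ordered_ids), x$source_size))
  if (!is.null(x$exclusion_radius))
    cat(sprintf(", exclusion radius %.3g", x$exclusion_radius))
  if (!is.null(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat("\n")
  invisible(x)
}

#' Directed sphere-exclusion selection
#'
#' Greedy diverse-subset selection: candidates are visited in a fixed
#' deterministic ("directed") order and a candidate is selected iff its
#' Tanimoto distance (1 - similarity) to every already-selected compound is
#' at least `radius` (a candidate exactly on the boundary is selectable).
#' Selection stops when `max_size` compounds have been accepted or the pool
#' is exhausted. The returned order is the selection order, so the first
#' `k` ids form the size-`k` library of a nested ladder.
#'
#' Visit orders: `"hashed"` (default) sorts candidates by a fixed 64-bit
#' hash of the canonical SMILES — deterministic, independent of file order,
#' and structurally uncorrelated, so every selection prefix spreads across
#' the pool rather than crawling through lexicographic neighborhoods;
#' `"canonical"` sorts by canonical SMILES bytewise; `"input"` keeps the
#' pool order; `"similarity_to_probes"` visits by descending maximum
#' Tanimoto similarity to a supplied probe fingerprint list.
#'
#' @param fps a [radial_fingerprints()] result (named feature-set list).
#' @param radius exclusion sphere size as Tanimoto distance, in (0, 1);
#'   the standard setting is 0.4 (i.e. no two selected compounds more
#'   similar than 0.6).
#' @param max_size maximum number of compounds to select.
#' @param ordering visit-order mode, see Details.
#' @param probes fingerprint list for `"similarity_to_probes"`.
#' @return A `selection_result` with `ordered_ids` in selection order.
#' @export
sphere_exclusion_select <- function(fps, radius = 0.4,
                                    max_size = length(fps),
                                    ordering = c("hashed", "canonical",
                                                 "input",
                                                 "similarity_to_probes"),
                                    probes = NULL) {
  ordering <- match.arg(ordering)
  if (length(fps) == 0L) stop("empty fingerprint list")
  if (!(radius > 0 && radius < 1)) stop("radius outside (0,1)")
  if (max_size < 1L) stop("max_size must be >= 1")

  ix <- .fp_index(fps)
  visit <- switch(ordering,
    hashed = {
      smi <- attr(fps, "smiles")
      if (is.null(smi)) stop("hashed ordering needs the 'smiles' attribute ",
                             "(use radial_fingerprints on a collection)")
      order(cpp_string_hash64(unname(smi)), method = "radix")
    },
    canonical = {
      smi <- attr(fps, "smiles")
      if (is.null(smi)) stop("canonical ordering needs the 'smiles' attribute ",
                             "(use radial_fingerprints on a collection)")
      order(smi, method = "radix")
    },
    input = seq_along(fps),
    similarity_to_probes = {
      if (is.null(probes) || length(probes) == 0L)
        stop("ordering 'similarity_to_probes' needs a non-empty probe list")
      both <- .fp_index(c(unclass(fps), unclass(probes)))
      nf <- length(fps)
      sim <- cpp_max_sim_to_set(both$sets, seq_len(nf),
                                nf + seq_along(probes))
      order(-sim, seq_len(nf), method = "radix")
    })

  sel <- cpp_sphere_exclusion(ix$sets, as.integer(visit), radius,
                              as.integer(min(max_size, length(fps))))
  .new_selection_result("sphere_exclusion", names(fps)[sel],
                        source_size = length(fps),
                        exclusion_radius = radius, ordering = ordering)
}

#' Seeded uniform random selection (control)
#'
#' Draws `n` records without replacement via a seeded pseudorandom
#' permutation of the pool; the same seed and pool order always reproduce
#' the same result. The calling session's RNG state is left untouched.
#'
#' @param col a [fragment_collection()] (or any object with ids via
#'   `names()` / `$id`).
#' @param n number of compounds to draw, `1 <= n <=` pool size.
#' @param seed integer seed.
#' @return A `selection_result` with `ordered_ids` in draw order.
#' @export
random_select <- function(col, n, seed) {
  ids <- if (inherits(col, "fragment_collection")) col$id
         else if (!is.null(names(col))) names(col)
         else as.character(col)
  if (n < 1L || n > length(ids))
    stop("n must be between 1 and the pool size (", length(ids), ")")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  picked <- sample(ids, n)
  .new_selection_result("random", picked, source_size = length(ids),
                        seed = as.integer(seed))
}

#' Nested size-ladder prefixes of a selection
#'
#' The size-`k` library is the first `k` ids of the selection order, so the
#' ladder libraries are nested: each smaller library is a subset of every
#' larger one.
#'
#' @param result a `selection_result`.
#' @param sizes ascending integer library sizes, all `<=` the selection
#'   length.
#' @return named list of id vectors, one per size.
#' @export
nested_prefixes <- function(result, sizes) {
  stopifnot(inherits(result, "selection_result"))
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be strictly ascending")
  if (max(sizes) > length(result$ordered_ids))
    stop("requested size ", max(sizes), " exceeds selection length ",
         length(result$ordered_ids))
  stats::setNames(lapply(sizes, function(k) result$ordered_ids[seq_len(k)]),
                  sizes)
}

#' Audit the sphere-exclusion guarantees of a selection
#'
#' Recomputes, by brute force over all pairs, the minimum pairwise Tanimoto
#' distance among selected compounds, and (for pools not truncated by
#' `max_size`) the maximum distance from any unselected compound to its
#' nearest selected neighbor.
#'
#' @param fps the fingerprint list the selection was made from.
#' @param result a sphere-exclusion `selection_result`.
#' @return list with `min_pairwise_distance`, `max_unselected_distance`
#'   (`NA` when every compound was selected), and the logical flags
#'   `separation_ok` and `coverage_ok` (the latter `NA` unless the pool was
#'   exhausted).
#' @export
audit_sphere_exclusion <- function(fps, result) {
  stopifnot(inherits(result, "selection_result"),
            result$method == "sphere_exclusion")
  ix <- .fp_index(fps)
  sel <- match(result$ordered_ids, names(fps))
  if (anyNA(sel)) stop("selection ids not found in fingerprint list")
  min_d <- if (length(sel) > 1L)
    1 - cpp_max_pairwise_sim(ix$sets, as.integer(sel)) else NA_real_
  unsel <- setdiff(seq_along(fps), sel)
  if (length(unsel)) {
    d_unsel <- 1 - cpp_max_sim_to_set(ix$sets, as.integer(unsel),
                                      as.integer(sel))
    max_unsel <- max(d_unsel)
  } else max_unsel <- NA_real_
  r <- result$exclusion_radius
  list(min_pairwise_distance = min_d,
       max_unselected_distance = max_unsel,
       separation_ok = if (is.na(min_d)) TRUE else min_d >= r - 1e-12,
       coverage_ok = if (length(unsel)) max_unsel < r else NA)
}
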