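# Radial (extended-connectivity) fingerprints as sets of 64-bit feature
# identifiers, pooled feature-abundance tables, and Tanimoto similarity.

#' Radial fingerprints for a fragment collection
#'
#' Each molecule is described by the set of its atom environments: iteration
#' 0 hashes per-atom connectivity invariants (element, heavy-atom degree,
#' formal charge, attached hydrogens, ring membership); every further
#' iteration extends each environment by one bond shell, folding in the
#' neighbors' previous identifiers together with the connecting bond orders.
#' Environments of all radii `0..n_iterations` are emitted (the cumulative
#' extended-connectivity convention). Identifiers live in the full 64-bit
#' space and are reported as 16-digit hex strings; they are never folded to
#' a short bit vector, so hash collisions are negligible.
#'
#' @param col a [fragment_collection()] (or a character vector of SMILES,
#'   canonicalized on entry).
#' @param n_iterations number of radial iterations (bond radius); the
#'   standard setting is 3.
#' @param emit_radius0 emit the radius-0 (single-atom) environments; the
#'   default `TRUE` matches the cumulative convention, `FALSE` drops them.
#' @return An object of class `fingerprint_set_list`: a named list (names =
#'   record ids) of character vectors of sorted feature identifiers, with
#'   the canonical SMILES attached as attribute `smiles`.
#' @examples
#' \donttest{
#' fps <- radial_fingerprints(fragment_collection(c("CCO", "CCN")))
#' lengths(fps)
#' }
#' @export
radial_fingerprints <- function(col, n_iterations = 3L, emit_radius0 = TRUE) {
  if (!inherits(col, "fragment_collection"))
    col <- fragment_collection(col)
  stopifnot(n_iterations >= 0L)
  graphs <- mol_graphs(col$smiles)
  fps <- lapply(graphs, function(g) {
    f <- cpp_radial_features(g$atoms, g$bonds, as.integer(n_iterations))
    if (!emit_radius0 && n_iterations > 0L) {
      r0 <- cpp_radial_features(g$atoms, g$bonds, 0L)
      f <- setdiff(f, r0)
    }
    sort(f)
  })
  names(fps) <- col$id
  structure(fps, smiles = stats::setNames(col$smiles, col$id),
            class = "fingerprint_set_list")
}

#' @export
print.fingerprint_set_list <- function(x, ...) {
  cat(sprintf("fingerprint_set_list: %d molecule(s), %d distinct feature(s)\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}

#' @export
`[.fingerprint_set_list` <- function(x, i) {
  out <- unclass(x)[i]
  structure(out, smiles = attr(x, "smiles")[i], class = "fingerprint_set_list")
}

#' Pool per-molecule fingerprints into a feature-abundance table
#'
#' Presence counting: a molecule contributes each of its distinct features
#' once, so `counts[f]` is the number of library members containing feature
#' `f`. Richness and the proportional abundances `p_i = n_i / total` are
#' both derived from this table.
#'
#' @param fps a [radial_fingerprints()] result or plain list of feature
#'   vectors.
#' @return An object of class `feature_abundance`: a named integer vector of
#'   counts with attribute `total`.
#' @export
pooled_abundance <- function(fps) {
  if (length(fps) == 0L) stop("empty fingerprint list")
  feats <- unlist(lapply(fps, unique), use.names = FALSE)
  tab <- table(feats)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(counts, total = sum(counts), class = "feature_abundance")
}

#' @export
print.feature_abundance <- function(x, ...) {
  cat(sprintf("feature_abundance: %d feature(s), total count %d\n",
              length(x), attr(x, "total")))
  invisible(x)
}

#' Tanimoto similarity between two feature sets
#'
#' `|A intersect B| / |A union B|`; symmetric, 1 exactly for equal sets, 0
#' for disjoint sets. Undefined (error) when both sets are empty.
#'
#' @param a,b character vectors of feature identifiers (treated as sets).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Tanimoto similarity is undefined for two empty sets")
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

# Map a list of feature-identifier vectors onto integer indices into the
# shared feature universe; sorted integer sets feed the C++ kernels.
.fp_index <- function(fps) {
  u <- unique(unlist(fps, use.names = FALSE))
  idx <- lapply(fps, function(f) sort(match(f, u)))
  list(sets = idx, universe = u)
}

#' Export fingerprints as an audit table
#'
#' @param fps a [radial_fingerprints()] result.
#' @return data.frame with columns `id` and `features` (space-separated
#'   sorted identifiers).
#' @export
fingerprint_table <- function(fps) {
  data.frame(id = names(fps),
             features = vapply(fps, function(f) paste(sort(f), collapse = " "),
                               character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
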