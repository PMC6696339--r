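# Reading, canonicalizing, deduplicating and writing fragment collections.

#' Build a fragment collection
#'
#' A fragment collection is an ordered set of molecules, each with a unique
#' identifier, a canonical SMILES, and a fluorine-atom count. It is the common
#' currency of the filtering, fingerprinting and selection steps.
#'
#' @param smiles character vector of SMILES strings (canonicalized on entry).
#' @param id character vector of identifiers; generated (`M000001`, ...) when
#'   `NULL`.
#' @param provenance free-text source tag stored with the collection.
#' @param canonicalize if `FALSE`, `smiles` is trusted to be canonical
#'   already (used internally to avoid redundant round trips).
#' @return An object of class `fragment_collection`: a data.frame with
#'   columns `id`, `smiles` (canonical) and `n_fluorine`, plus a
#'   `provenance` attribute.
#' @examples
#' \donttest{
#' col <- fragment_collection(c("c1ccccc1", "CCO"), id = c("benz", "eth"))
#' nrow(col)
#' }
#' @export
fragment_collection <- function(smiles, id = NULL, provenance = "",
                                canonicalize = TRUE) {
  smiles <- as.character(smiles)
  if (canonicalize && length(smiles)) {
    can <- canonicalize_smiles(smiles)
    if (anyNA(can))
      stop("unparseable SMILES: ",
           paste(utils::head(smiles[is.na(can)], 5), collapse = ", "))
    smiles <- can
  }
  if (is.null(id)) id <- sprintf("M%06d", seq_along(smiles))
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate identifiers in collection: ",
         paste(utils::head(unique(id[duplicated(id)]), 5), collapse = ", "))
  df <- data.frame(id = id, smiles = smiles,
                   n_fluorine = .count_fluorines(smiles),
                   stringsAsFactors = FALSE)
  structure(df, provenance = provenance,
            class = c("fragment_collection", "data.frame"))
}

.count_fluorines <- function(smiles) {
  # count F atoms from the SMILES text: every aliphatic F is written as the
  # bare symbol "F" or in brackets; exclude Fe etc. (two-letter symbols are
  # bracketed in SMILES, so an unbracketed F is always fluorine)
  vapply(smiles, function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- 0L
    in_bracket <- FALSE
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "[") in_bracket <- TRUE
      else if (ch == "]") in_bracket <- FALSE
      else if (ch == "F") {
        nxt <- if (i < length(chars)) chars[i + 1L] else ""
        if (!(in_bracket && nxt %in% letters)) n <- n + 1L
      }
      i <- i + 1L
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.fragment_collection <- function(x, ...) {
  cat(sprintf("fragment_collection: %d record(s)", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(sprintf(" [%s]", prov))
  cat("\n")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Read a SMILES (.smi) file into a fragment collection
#'
#' Accepts the whitespace-delimited `SMILES [id]` convention: one molecule
#' per line, an optional identifier after the structure, `#` lines as
#' comments. Unparseable lines are skipped with a message giving their
#' count; an error is raised only when no line parses at all.
#'
#' @param path path to the file.
#' @param id_policy `"from_column"` uses the second whitespace-delimited
#'   token as the identifier (generating one when the token is absent);
#'   `"generated"` always numbers records `M000001`, ...
#' @return A [fragment_collection()] in file line order. The number of
#'   skipped lines is available as attribute `n_unparseable`.
#' @export
read_smiles <- function(path, id_policy = c("from_column", "generated")) {
  id_policy <- match.arg(id_policy)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("zero parseable structures in ", path)

  toks <- strsplit(lines, "[ \t]+")
  smi <- vapply(toks, `[[`, character(1), 1L)
  rawid <- vapply(toks, function(t) if (length(t) >= 2) t[[2]] else NA_character_,
                  character(1))

  can <- canonicalize_smiles(smi)
  ok <- !is.na(can)
  n_bad <- sum(!ok)
  if (!any(ok)) stop("zero parseable structures in ", path)
  if (n_bad)
    message(n_bad, " unparseable line(s) skipped in ", path)

  ids <- if (id_policy == "from_column") {
    out <- rawid[ok]
    gen <- is.na(out)
    out[gen] <- sprintf("M%06d", which(ok)[gen])
    out
  } else sprintf("M%06d", seq_len(sum(ok)))

  col <- fragment_collection(can[ok], id = ids, provenance = path,
                             canonicalize = FALSE)
  attr(col, "n_unparseable") <- n_bad
  col
}

#' Remove duplicate structures from a collection
#'
#' Two records are duplicates when their canonical SMILES coincide; the first
#' occurrence (in collection order) is kept, so the result is stable across
#' repeated reads of the same file.
#'
#' @param col a [fragment_collection()].
#' @return The deduplicated collection.
#' @export
dedup_canonical <- function(col) {
  stopifnot(inherits(col, "fragment_collection"))
  keep <- !duplicated(col$smiles)
  out <- col[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(col, "provenance"),
            class = class(col))
}

#' Write a fragment collection to a SMILES file
#'
#' One `SMILES id` line per record. Whitespace inside identifiers would break
#' the two-token format, so it is replaced by underscores.
#'
#' @param col a non-empty [fragment_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(col, path) {
  stopifnot(inherits(col, "fragment_collection"))
  if (nrow(col) == 0L) stop("refusing to write an empty collection")
  ids <- gsub("[ \t]+", "_", col$id)
  writeLines(paste(col$smiles, ids), path)
  invisible(path)
}

#' Summarize a collection as a data.frame for CSV export
#'
#' @param col a [fragment_collection()].
#' @return data.frame with columns `id`, `canonical_smiles`, `n_fluorine`.
#' @export
collection_summary <- function(col) {
  stopifnot(inherits(col, "fragment_collection"))
  data.frame(id = col$id, canonical_smiles = col$smiles,
             n_fluorine = col$n_fluorine, stringsAsFactors = FALSE)
}
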