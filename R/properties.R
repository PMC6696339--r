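# Physicochemical descriptors and the three library filters: adapted
# Rule-of-3 bounds, reactive-group SMARTS, and fluorine count.

# Apply a per-molecule OpenBabel function over the collection's SMILES,
# returning a list in record order.
.ob_apply <- function(smiles, f) {
  src <- paste0(smiles, " q", seq_along(smiles), collapse = "\n")
  ChemmineOB::forEachMol("SMILES", paste0(src, "\n"), f)
}

# Rotatable bonds, strict: non-ring single bonds between two non-terminal
# heavy atoms, excluding triple-bond termini and amide C-N bonds.
.rb_smarts_basic <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
.rb_smarts_amide <- "[NX3;!D1]-!@[CX3]=[OX1]"

#' Compute physicochemical properties for every record of a collection
#'
#' Descriptors used by the adapted Rule-of-3 filter: molecular weight (Da),
#' computed logP (atom-contribution estimate), ring count (smallest set of
#' smallest rings, i.e. the circuit rank of the heavy-atom graph),
#' hydrogen-bond donors and acceptors (Lipinski-style counts of the
#' underlying chemistry toolkit), rotatable bonds (strict: excludes amide
#' C-N bonds and terminal/triple bonds), and topological polar surface area
#' (A^2).
#'
#' The donor/acceptor/rotatable counters are pluggable: pass a function
#' taking the collection and returning an integer vector to replace any of
#' them.
#'
#' @param col a [fragment_collection()].
#' @param hbd_fun,hba_fun,rb_fun optional replacement counting functions.
#' @return data.frame with one row per record: `id`, `mw`, `logp`,
#'   `n_rings`, `hbd`, `hba`, `rb`, `psa`, `n_fluorine`.
#' @export
compute_properties <- function(col, hbd_fun = NULL, hba_fun = NULL,
                               rb_fun = NULL) {
  stopifnot(inherits(col, "fragment_collection"))
  if (nrow(col) == 0L)
    return(data.frame(id = character(0), mw = numeric(0), logp = numeric(0),
                      n_rings = integer(0), hbd = integer(0), hba = integer(0),
                      rb = integer(0), psa = numeric(0),
                      n_fluorine = integer(0)))
  rows <- .ob_apply(col$smiles, function(mol) {
    p <- ChemmineOB::prop_OB(mol)
    rb_b <- ChemmineOB::smartsSearch_OB(list(mol), .rb_smarts_basic)
    rb_a <- ChemmineOB::smartsSearch_OB(list(mol), .rb_smarts_amide)
    c(mw = p$MW, logp = p$logP, hbd = p$HBD, hba = p$HBA1, psa = p$TPSA,
      rb = max(rb_b - rb_a, 0))
  })
  pr <- as.data.frame(do.call(rbind, rows))
  graphs <- mol_graphs(col$smiles)
  n_rings <- vapply(graphs, .ring_count, integer(1))
  hbd <- if (is.null(hbd_fun)) as.integer(pr$hbd) else as.integer(hbd_fun(col))
  hba <- if (is.null(hba_fun)) as.integer(pr$hba) else as.integer(hba_fun(col))
  rb <- if (is.null(rb_fun)) as.integer(pr$rb) else as.integer(rb_fun(col))
  data.frame(id = col$id, mw = pr$mw, logp = pr$logp, n_rings = n_rings,
             hbd = hbd, hba = hba, rb = rb, psa = pr$psa,
             n_fluorine = col$n_fluorine, stringsAsFactors = FALSE)
}

#' Adapted Rule-of-3 bounds for fragment libraries
#'
#' The default rule set retains compounds with 100 <= MW <= 300 Da,
#' logP <= 3, at most 3 rings, at most 3 hydrogen-bond donors and
#' acceptors, at most 3 rotatable bonds, and polar surface area <= 60 A^2.
#' The MW floor removes trivially small species that bring little binding
#' information.
#'
#' @return data.frame with columns `property`, `lower`, `upper`.
#' @export
default_rule_of_3 <- function() {
  data.frame(
    property = c("mw", "logp", "n_rings", "hbd", "hba", "rb", "psa"),
    lower = c(100, -Inf, 0, 0, 0, 0, 0),
    upper = c(300, 3, 3, 3, 3, 3, 60),
    stringsAsFactors = FALSE
  )
}

#' Read filter rules from a configuration file
#'
#' Whitespace-delimited lines `property lower upper` (use `-Inf`/`Inf` for
#' open bounds); `#` starts a comment.
#'
#' @param path path to the rules file.
#' @return data.frame with columns `property`, `lower`, `upper`.
#' @export
read_filter_rules <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("property", "lower", "upper"),
                          stringsAsFactors = FALSE)
  if (any(df$lower > df$upper)) stop("rule with lower > upper in ", path)
  df
}

#' Filter a collection by physicochemical property bounds
#'
#' Retains exactly the records whose property vector satisfies every rule;
#' per-rule rejection counts and a per-record rejection table (`id`,
#' `failed_rule`) are attached as attributes `rule_counts` and `rejections`.
#'
#' @param col a [fragment_collection()].
#' @param rules data.frame of bounds as from [default_rule_of_3()]; an empty
#'   rule set is the identity.
#' @param properties optional precomputed table from [compute_properties()]
#'   (recomputed when `NULL`).
#' @return The filtered collection.
#' @export
rule_of_3_filter <- function(col, rules = default_rule_of_3(),
                             properties = NULL) {
  stopifnot(inherits(col, "fragment_collection"))
  if (nrow(rules %||% data.frame()) == 0L || nrow(col) == 0L) {
    attr(col, "rule_counts") <- stats::setNames(integer(0), character(0))
    attr(col, "rejections") <- data.frame(id = character(0),
                                          failed_rule = character(0))
    return(col)
  }
  if (is.null(properties)) properties <- compute_properties(col)
  stopifnot(all(rules$property %in% names(properties)))
  if (any(rules$lower > rules$upper)) stop("rule with lower > upper")

  fails <- matrix(FALSE, nrow(col), nrow(rules))
  for (r in seq_len(nrow(rules))) {
    v <- properties[[rules$property[r]]]
    fails[, r] <- v < rules$lower[r] | v > rules$upper[r]
  }
  rule_names <- sprintf("%s[%s,%s]", rules$property, rules$lower, rules$upper)
  keep <- rowSums(fails) == 0L
  rej <- which(!keep)
  rej_rules <- vapply(rej, function(i)
    paste(rule_names[fails[i, ]], collapse = ";"), character(1))

  out <- col[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, provenance = attr(col, "provenance"),
                   class = class(col))
  attr(out, "rule_counts") <- stats::setNames(colSums(fails), rule_names)
  attr(out, "rejections") <- data.frame(id = col$id[rej],
                                        failed_rule = rej_rules,
                                        stringsAsFactors = FALSE)
  out
}

#' Default reactive-group SMARTS patterns
#'
#' A small curated set of electrophilic or unstable motifs commonly excluded
#' from screening libraries (acyl halides, aldehydes, Michael acceptors,
#' alkyl halides, anhydrides, isocyanates, strained heterocycles, peroxides,
#' thioesters, azides). Shipped as an editable text file in
#' `inst/extdata/reactive_smarts.txt`; edit or replace it to change the
#' policy.
#'
#' @return named character vector of SMARTS patterns.
#' @export
default_reactive_smarts <- function() {
  path <- system.file("extdata", "reactive_smarts.txt", package = "fragdiv")
  read_smarts_file(path)
}

#' Read a named SMARTS pattern file
#'
#' Lines of `name<whitespace>SMARTS`; lines beginning with `#` are comments
#' (`#` inside a pattern is the SMARTS atomic-number primitive and is kept).
#'
#' @param path path to the pattern file.
#' @return named character vector of SMARTS.
#' @export
read_smarts_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  stats::setNames(vapply(toks, `[[`, character(1), 2L),
                  vapply(toks, `[[`, character(1), 1L))
}

#' Remove records matching reactive-group substructure patterns
#'
#' A record is removed when it matches any pattern; per-pattern match counts
#' are attached as attribute `pattern_counts` and per-record hits as
#' attribute `rejections`.
#'
#' @param col a [fragment_collection()].
#' @param patterns named character vector of SMARTS; empty set is the
#'   identity.
#' @return The filtered collection.
#' @export
reactive_group_filter <- function(col, patterns = default_reactive_smarts()) {
  stopifnot(inherits(col, "fragment_collection"))
  if (length(patterns) == 0L || nrow(col) == 0L) {
    attr(col, "pattern_counts") <- stats::setNames(integer(0), character(0))
    attr(col, "rejections") <- data.frame(id = character(0),
                                          failed_rule = character(0))
    return(col)
  }
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    names(patterns) <- patterns
  # validate every pattern up front so a bad one is reported by name
  .ob_apply("C", function(mol) {
    for (p in seq_along(patterns))
      tryCatch(ChemmineOB::smartsSearch_OB(list(mol), patterns[[p]]),
               error = function(e)
                 stop("invalid SMARTS pattern '", names(patterns)[p], "': ",
                      patterns[[p]], call. = FALSE))
    NULL
  })
  hits_rows <- .ob_apply(col$smiles, function(mol)
    vapply(patterns, function(pt)
      ChemmineOB::smartsSearch_OB(list(mol), pt) > 0, logical(1)))
  hits <- do.call(rbind, hits_rows)
  dim(hits) <- c(nrow(col), length(patterns))
  keep <- rowSums(hits) == 0L
  rej <- which(!keep)
  rej_rules <- vapply(rej, function(i)
    paste(names(patterns)[hits[i, ]], collapse = ";"), character(1))
  out <- col[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, provenance = attr(col, "provenance"),
                   class = class(col))
  attr(out, "pattern_counts") <- stats::setNames(colSums(hits), names(patterns))
  attr(out, "rejections") <- data.frame(id = col$id[rej],
                                        failed_rule = rej_rules,
                                        stringsAsFactors = FALSE)
  out
}

#' Retain records by fluorine-atom count
#'
#' The fluorinated-library workflow keeps fragments carrying 1 to 3 fluorine
#' atoms (the range most useful for 19F NMR screening).
#'
#' @param col a [fragment_collection()].
#' @param min_f,max_f inclusive bounds on the fluorine count.
#' @return The filtered collection; rejections attached as attribute
#'   `rejections`.
#' @export
fluorine_filter <- function(col, min_f = 1L, max_f = 3L) {
  stopifnot(inherits(col, "fragment_collection"))
  if (min_f > max_f) stop("min_f > max_f")
  if (min_f < 0L) stop("min_f must be >= 0")
  keep <- col$n_fluorine >= min_f & col$n_fluorine <= max_f
  out <- col[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, provenance = attr(col, "provenance"),
                   class = class(col))
  attr(out, "rejections") <- data.frame(
    id = col$id[!keep],
    failed_rule = rep(sprintf("n_fluorine[%d,%d]", min_f, max_f), sum(!keep)),
    stringsAsFactors = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
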