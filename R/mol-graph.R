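# Internal bridge to OpenBabel (via ChemmineOB/ChemmineR): canonicalization
# and extraction of molecule graphs (atoms, bonds, ring membership) that feed
# the radial fingerprinter.

# Atomic numbers for the elements a fragment catalogue can realistically
# contain; anything else still gets a stable (negative rank) code.
.elements <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
               S = 16, Cl = 17, Br = 35, I = 53)

.atomic_number <- function(sym) {
  z <- unname(.elements[sym])
  miss <- is.na(z)
  if (any(miss)) z[miss] <- -match(sym[miss], unique(sym[miss]))
  as.integer(z)
}

# MDL atom-block charge codes (old-style column): 0=0, 1=+3, 2=+2, 3=+1,
# 4=radical, 5=-1, 6=-2, 7=-3.
.charge_from_code <- function(code) {
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  out <- map[as.integer(code) + 1L]
  out[is.na(out)] <- 0L
  out
}

.ob_convert <- function(from, to, source, add_h = FALSE) {
  # no gen2D: coordinates are irrelevant for connectivity work and slow
  opts <- if (add_h) data.frame(names = "h", args = "")
          else data.frame(names = character(0), args = character(0))
  ChemmineOB::convertFormat(from, to, source = source, options = opts)
}

# Canonicalize a character vector of SMILES. Returns NA for strings OpenBabel
# cannot parse. OpenBabel aborts a multi-molecule stream at the first bad
# line, so missing outputs are re-tried by bisection down to singletons;
# outputs are matched back by an injected per-line label.
canonicalize_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  res <- rep(NA_character_, n)
  blank <- !nzchar(trimws(smiles))
  todo <- which(!blank)

  fill <- function(idx) {
    src <- paste0(smiles[idx], " q", idx, collapse = "\n")
    out <- tryCatch(
      suppressWarnings(.ob_convert("SMI", "CAN", paste0(src, "\n"))),
      error = function(e) ""
    )
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) == 2L && grepl("^q[0-9]+$", parts[2]) && nzchar(parts[1]))
        res[as.integer(sub("^q", "", parts[2]))] <<- parts[1]
    }
    bad <- idx[is.na(res[idx])]
    if (length(bad) && length(idx) > 1L) {
      half <- ceiling(length(bad) / 2)
      if (length(bad) == length(idx) && length(bad) > 1L) {
        # whole chunk failed: split
        fill(bad[seq_len(half)])
        fill(bad[-seq_len(half)])
      } else if (length(bad) < length(idx)) {
        fill(bad)
      }
    }
  }
  if (length(todo)) fill(todo)
  res
}

# Parse SMILES (assumed valid) into molecule graphs. Returns an unnamed list,
# one element per molecule: list(atoms = n x 5 integer matrix with columns
# z, degree, charge, n_h, in_ring; bonds = m x 3 integer matrix i, j, order
# over heavy atoms only). Hydrogens are folded into the n_h invariant.
mol_graphs <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(list())
  src <- paste0(smiles, " g", seq_len(n), collapse = "\n")
  sdftxt <- suppressWarnings(.ob_convert("SMI", "SDF", paste0(src, "\n"),
                                         add_h = TRUE))
  con <- textConnection(sdftxt)
  on.exit(close(con))
  sdfs <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con))
  titles <- vapply(ChemmineR::SDFset2SDF(sdfs), function(x)
    unname(ChemmineR::header(x)["Molecule_Name"]), character(1))
  pos <- match(paste0("g", seq_len(n)), titles)
  if (anyNA(pos))
    stop("SMILES could not be converted to a molecule graph: ",
         paste(smiles[is.na(pos)], collapse = ", "))

  lapply(pos, function(p) .graph_from_sdf(sdfs[[p]]))
}

.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_.*$", "", rownames(ab))
  natoms <- nrow(ab)
  charge_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, natoms)
  charge <- .charge_from_code(charge_col)

  if (is.null(bb) || length(bb) == 0L || (is.matrix(bb) && nrow(bb) == 0L)) {
    bi <- integer(0); bj <- integer(0); bo <- integer(0)
  } else {
    bm <- matrix(as.integer(as.matrix(bb)[, 1:3]), ncol = 3)
    bi <- bm[, 1]; bj <- bm[, 2]; bo <- bm[, 3]
  }

  heavy <- which(sym != "H")
  hmap <- integer(natoms)
  hmap[heavy] <- seq_along(heavy)

  n_h <- integer(length(heavy))
  keep <- logical(length(bi))
  for (b in seq_along(bi)) {
    hi <- sym[bi[b]] == "H"; hj <- sym[bj[b]] == "H"
    if (hi && hj) next
    if (hi) { n_h[hmap[bj[b]]] <- n_h[hmap[bj[b]]] + 1L; next }
    if (hj) { n_h[hmap[bi[b]]] <- n_h[hmap[bi[b]]] + 1L; next }
    keep[b] <- TRUE
  }
  ei <- hmap[bi[keep]]; ej <- hmap[bj[keep]]; eo <- bo[keep]

  nh <- length(heavy)
  degree <- tabulate(c(ei, ej), nbins = nh)

  in_ring <- integer(nh)
  if (length(ei)) {
    g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
    if (igraph::vcount(g) < nh) g <- igraph::add_vertices(g, nh - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_edge <- rep(TRUE, length(ei))
    if (length(br)) ring_edge[as.integer(br)] <- FALSE
    ring_atoms <- unique(c(ei[ring_edge], ej[ring_edge]))
    in_ring[ring_atoms] <- 1L
  }

  atoms <- cbind(z = .atomic_number(sym[heavy]),
                 degree = as.integer(degree),
                 charge = as.integer(charge[heavy]),
                 n_h = n_h,
                 in_ring = in_ring)
  bonds <- cbind(i = ei, j = ej, order = eo)
  storage.mode(atoms) <- "integer"
  storage.mode(bonds) <- "integer"
  list(atoms = atoms, bonds = bonds)
}

# SSSR-equivalent ring count (circuit rank) per molecule graph.
.ring_count <- function(graph) {
  nh <- nrow(graph$atoms)
  m <- nrow(graph$bonds)
  if (nh == 0L) return(0L)
  if (m == 0L) return(0L)
  g <- igraph::graph_from_edgelist(graph$bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < nh) g <- igraph::add_vertices(g, nh - igraph::vcount(g))
  comp <- igraph::components(g)$no
  as.integer(m - nh + comp)
}
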