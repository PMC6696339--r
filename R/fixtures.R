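# Seeded generator of fragment-like SMILES catalogues with controlled
# redundancy: analog families (shared scaffold + base substituent, varying
# decoration) plus unrelated singletons. Emulates the structure of a
# commercial fragment catalogue so selection and diversity metrics can be
# exercised fully offline.

# Scaffold templates: {A} is the family-defining slot, {B} the analog slot.
# Saturated scaffolds get a restricted substituent pool (no Cl/Br, which
# would create alkyl halides).
.scaffolds <- function() {
  data.frame(
    name = c("benzene_13", "benzene_14", "benzene_12", "pyridine_3",
             "pyridine_4", "pyrimidine", "pyrazine", "pyridazine", "furan",
             "thiophene", "pyrrole", "nme_pyrrole", "imidazole", "pyrazole",
             "oxazole", "isoxazole", "thiazole", "indole", "benzofuran",
             "benzothiophene", "benzimidazole", "quinoline", "naphthalene",
             "biphenyl", "cyclopropylbenzene", "isoquinoline", "quinazoline",
             "quinoxaline", "benzoxazole", "benzothiazole", "benzodioxole",
             "chromane", "nme_thq", "pyrrolopyridine", "imidazopyridine",
             "thienopyridine", "nme_pyridone", "cyclohexane", "cyclopentane",
             "piperidine", "nme_piperidine", "morpholine", "oxane",
             "oxolane", "cyclohexene"),
    template = c("c1cc({A})cc({B})c1", "c1cc({A})ccc1{B}",
                 "c1ccc({A})c({B})c1", "c1cc({A})cnc1{B}",
                 "c1cc({A})ncc1{B}", "c1nc({A})ncc1{B}", "c1nc({A})cnc1{B}",
                 "c1cc({A})nnc1{B}", "c1cc({A})oc1{B}", "c1cc({A})sc1{B}",
                 "c1cc({A})[nH]c1{B}", "c1cc({A})n(C)c1{B}",
                 "c1nc({A})[nH]c1{B}", "c1c({B})c({A})n[nH]1",
                 "c1oc({A})nc1{B}", "c1c({B})c({A})on1", "c1sc({A})nc1{B}",
                 "c1cc({B})c2c(c1)c({A})c[nH]2", "c1cc({B})c2c(c1)cc({A})o2",
                 "c1cc({B})c2c(c1)cc({A})s2", "c1cc({B})c2c(c1)nc({A})[nH]2",
                 "c1cc({B})c2c(c1)ccc({A})n2", "c1cc({B})c2cc({A})ccc2c1",
                 "c1cc({B})cc(-c2ccc({A})cc2)c1", "c1cc(C2CC2)cc({B})c1{A}",
                 "c1cc({B})c2cc({A})ncc2c1", "c1cc({B})c2nc({A})ncc2c1",
                 "c1cc({B})c2nc({A})cnc2c1", "c1cc({B})c2oc({A})nc2c1",
                 "c1cc({B})c2sc({A})nc2c1", "c1cc({B})c2c(c1{A})OCO2",
                 "C1CC({A})c2cc({B})ccc2O1", "CN1CCC({A})c2cc({B})ccc21",
                 "c1cc({B})c2[nH]c({A})cc2n1", "c1cc({B})n2cc({A})nc2c1",
                 "c1cc({B})c2cc({A})sc2n1", "O=c1cc({A})cc({B})n1C",
                 "C1CC({B})CC({A})C1", "C1CC({B})C({A})C1",
                 "C1C({B})C({A})CNC1", "CN1CC({B})C({A})CC1",
                 "O1CC({A})NC({B})C1", "C1CC({B})C({A})OC1",
                 "C1C({B})C({A})CO1", "C1=CC({B})C({A})CC1"),
    aromatic = c(rep(TRUE, 37), rep(FALSE, 8)),
    stringsAsFactors = FALSE)
}

# Family-defining substituents ({A} slot): substantial groups, so analogs
# within a family share a large common core. Ring-bearing entries carry an
# optional {X} decoration slot that varies WITHIN a family, multiplying the
# analog space. All entries are fluorine-free; fluorinated decorations are
# applied only through .fluor_subs (on the {B} slot) so the 1-3 fluorine
# budget is controlled exactly.
.subs_family_a <- c("c2ccc({X})cc2", "c2cc({X})ccc2", "c2c({X})cccc2",
                    "Cc2ccc({X})cc2", "Cc2cc({X})ccc2", "Oc2ccc({X})cc2",
                    "Oc2cc({X})ccc2", "OCc2ccc({X})cc2", "c2ccc({X})o2",
                    "c2cc({X})co2", "c2ccc({X})s2", "c2cc({X})cs2",
                    "c2ccc({X})cn2", "c2ccc({X})nc2", "c2cc({X})cnc2",
                    "Cn2cc({X})cn2", "c2nc({X})cs2", "c2nc({X})co2",
                    "N2CC({X})C2", "OC2CCC({X})CC2", "C2CCC({X})CC2",
                    "N2CCC({X})CC2")
# family substituents without a decoration slot: used for one-off
# (singleton) structures only, where analog depth is not needed
.subs_single_a <- c("C2CC2", "C2CCCC2", "N2CCOCC2", "N2CCCC2", "OCC",
                    "OCCO", "CCO", "C(C)O", "N(C)C", "CC#N", "C(=O)OC",
                    "S(C)(=O)=O", "OC(C)C", "NC(C)=O", "CN(C)C", "OCC#N")
.subs_x <- c("", "C", "CC", "O", "OC", "N", "Cl", "C#N")

# Analog-variation ({B} slot) homolog ladders: a family walks ONE ladder,
# so most members have a one-carbon (or halogen-swap) neighbor — the
# near-duplicate structure that makes commercial catalogues redundant.
# Saturated scaffolds exclude the halogen ladder (an aliphatic Cl/Br would
# be a reactive alkyl halide).
.b_ladders <- list(alkyl = c("", "C", "CC", "CCC", "C(C)C", "CCCC",
                             "CC(C)C"),
                   alkoxy = c("O", "OC", "OCC", "OC(C)C", "OCCC",
                              "OCC(C)C"),
                   hydroxyalkyl = c("CO", "CCO", "C(C)O", "CCCO", "CC(C)O",
                                    "CCC(C)O"),
                   aminoalkyl = c("N", "NC", "NCC", "N(C)C", "NC(C)C",
                                  "NCCC"),
                   nitrile = c("C#N", "CC#N", "CCC#N", "C(C)C#N",
                               "CC(C)C#N"),
                   halo = c("F", "Cl", "Br", "C", "CC", "C(C)C"))
.b_ladders_saturated <- setdiff(names(.b_ladders), "halo")
.fluor_subs <- c("F", "C(F)F", "C(F)(F)F", "OC(F)(F)F")

# Fill one {slot}; an empty substituent removes its enclosing branch.
.fill_slot <- function(s, slot, sub) {
  pat <- paste0("{", slot, "}")
  if (!grepl(pat, s, fixed = TRUE)) return(s)
  if (nzchar(sub)) sub(pat, sub, s, fixed = TRUE)
  else sub(pat, "",
           sub(paste0("(", pat, ")"), "", s, fixed = TRUE), fixed = TRUE)
}

.assemble <- function(template, a, b) {
  .fill_slot(.fill_slot(template, "A", a), "B", b)
}

#' Specification for a synthetic fragment catalogue
#'
#' @param n_total target number of unique, filter-compliant fragments
#'   (capped at 20,000: the generator targets desk-scale benchmarking, not
#'   catalogue-scale realism).
#' @param n_families number of analog families (each family shares a
#'   scaffold and a base substituent and varies a second decoration site).
#' @param family_size_mean average analogs per family; derived from
#'   `n_total`, `n_families` and `singleton_fraction` when `NULL`.
#' @param singleton_fraction share of the catalogue built as unrelated
#'   one-off structures.
#' @param fluorination_rate probability that a generated fragment carries a
#'   fluorinated decoration (1-3 fluorine atoms).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_total = 5000L, n_families = 400L,
                         family_size_mean = NULL, singleton_fraction = 0.1,
                         fluorination_rate = 0.3, seed = 1L) {
  stopifnot(n_total >= 1, n_families >= 0, n_total >= n_families,
            singleton_fraction >= 0, singleton_fraction <= 1,
            fluorination_rate >= 0, fluorination_rate <= 1)
  if (n_total > 20000L) stop("fixture sizes are capped at 20,000")
  if (is.null(family_size_mean))
    family_size_mean <- if (n_families > 0)
      n_total * (1 - singleton_fraction) / n_families else 0
  structure(list(n_total = as.integer(n_total),
                 n_families = as.integer(n_families),
                 family_size_mean = family_size_mean,
                 singleton_fraction = singleton_fraction,
                 fluorination_rate = fluorination_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fragment catalogue
#'
#' Builds `n_total` unique, parseable, Rule-of-3-compliant fragments by
#' decorating a built-in list of ~45 fragment scaffolds with substituent
#' sets. Families are distinct (scaffold, family-substituent) pairs whose
#' members walk complete homolog ladders at a second decoration site, so
#' most members have a one-carbon analog neighbor; singletons are one-off
#' random decorations. Candidates violating the default Rule-of-3 bounds
#' and canonical duplicates are dropped and regenerated until the target
#' count is reached.
#'
#' @param spec a [fixture_spec()].
#' @return A [fragment_collection()] with attributes `families` (named
#'   vector mapping record id to family label, `NA` for singletons) and
#'   `fixture_spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  sc <- .scaffolds()

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  ladders_for <- function(si) if (sc$aromatic[si]) names(.b_ladders)
                              else .b_ladders_saturated
  b_pool_for <- function(si)
    unique(unlist(.b_ladders[ladders_for(si)], use.names = FALSE))
  n_singletons <- if (spec$n_families == 0L) spec$n_total
                  else round(spec$n_total * spec$singleton_fraction)
  n_family_target <- spec$n_total - n_singletons

  # families = distinct (scaffold, family substituent) pairs; each family
  # additionally fixes a homolog ladder and three decoration values for the
  # family substituent's {X} slot, so its members share a large core.
  # Bases are screened once so every family has headroom under the
  # Rule-of-3 bounds for its decorated members.
  combos <- expand.grid(si = seq_len(nrow(sc)),
                        a = c(.subs_family_a, .subs_single_a),
                        stringsAsFactors = FALSE)
  combos$family_eligible <- combos$a %in% .subs_family_a
  base_smi <- vapply(seq_len(nrow(combos)), function(i)
    .assemble(sc$template[combos$si[i]],
              .fill_slot(combos$a[i], "X", ""), ""), character(1))
  base_can <- canonicalize_smiles(base_smi)
  ok <- !is.na(base_can)
  base_prop <- compute_properties(
    fragment_collection(base_can[ok], id = sprintf("B%04d", which(ok)),
                        canonicalize = FALSE))
  viable_ok <- with(base_prop, mw <= 255 & logp <= 3.0 & n_rings <= 3 &
                      hbd <= 3 & hba <= 3 & rb <= 3 & psa <= 58)
  viable <- which(ok)[viable_ok]
  combos$logp <- NA_real_
  combos$logp[ok] <- base_prop$logp
  viable_family <- viable[combos$family_eligible[viable]]
  if (spec$n_families > length(viable_family))
    stop("infeasible spec: only ", length(viable_family),
         " viable (scaffold, family substituent) pairs available")
  fam <- combos[sample(viable_family, spec$n_families), , drop = FALSE]
  # lipophilic bases only walk polar ladders, so their decorated members
  # stay inside the computed-logP bound
  polar_ladders <- c("alkoxy", "hydroxyalkyl", "aminoalkyl", "nitrile")
  fam_ladders <- lapply(seq_len(nrow(fam)), function(f) {
    pool <- ladders_for(fam$si[f])
    if (!is.na(fam$logp[f]) && fam$logp[f] > 2.4)
      pool <- intersect(pool, polar_ladders)
    sample(pool, min(2L, length(pool)))
  })
  # Families are laid out as COMPLETE homolog chains: for a decoration
  # value x of the family substituent, every rung of the family's ladder is
  # emitted, so nearly every member has a one-step homolog neighbor — the
  # near-duplicate texture that makes a commercial catalogue redundant.
  # Chains are emitted lazily, one per request, until the decoration space
  # (one chain per x value) is exhausted. A chain is either the plain
  # ladder or the fluorinated series; the per-chain fluorination
  # probability is chosen so the MEMBER fluorination fraction matches the
  # requested rate.
  fam_x_order <- lapply(seq_len(nrow(fam)), function(f) sample(.subs_x))
  fam_chains_used <- integer(nrow(fam))

  chain_fluor_prob <- function(L) {
    r <- spec$fluorination_rate
    nf <- length(.fluor_subs)
    r * L / (nf * (1 - r) + r * L)
  }

  family_chain <- function(f) {
    used <- fam_chains_used[f]
    nx <- length(.subs_x)
    n_max <- nx * length(fam_ladders[[f]])
    if (used >= n_max) return(NULL)
    x <- fam_x_order[[f]][used %% nx + 1L]
    ladder_name <- fam_ladders[[f]][used %/% nx + 1L]
    fam_chains_used[f] <<- used + 1L
    ladder <- .b_ladders[[ladder_name]]
    rungs <- if (stats::runif(1) < chain_fluor_prob(length(ladder)))
      .fluor_subs else ladder
    a <- .fill_slot(fam$a[f], "X", x)
    vapply(rungs, function(b) .assemble(sc$template[fam$si[f]], a, b),
           character(1), USE.NAMES = FALSE)
  }

  singleton_member <- function(fluorinate) {
    i <- sample(viable, 1L)
    si <- combos$si[i]
    a <- .fill_slot(combos$a[i], "X", sample(.subs_x, 1L))
    b <- if (fluorinate) sample(.fluor_subs, 1L)
         else sample(b_pool_for(si), 1L)
    .assemble(sc$template[si], a, b)
  }

  seen <- character(0)
  seen_raw <- new.env(parent = emptyenv()) # raw strings already tried
  acc <- list()
  n_fam_acc <- 0L
  n_singl_acc <- 0L
  rounds <- 0L

  accept_batch <- function(batch) {
    # batch: data.frame(smiles_raw, family). Canonicalize, keep compliant
    # unique survivors in batch order, capped at the per-category targets.
    can <- canonicalize_smiles(batch$smiles_raw)
    ok <- !is.na(can)
    batch <- batch[ok, , drop = FALSE]; can <- can[ok]
    first <- !duplicated(can) & !(can %in% seen)
    batch <- batch[first, , drop = FALSE]; can <- can[first]
    if (!nrow(batch)) return(invisible(NULL))
    tmp <- fragment_collection(can, id = sprintf("T%06d", seq_along(can)),
                               canonicalize = FALSE)
    filt <- rule_of_3_filter(tmp)
    keep <- match(filt$id, tmp$id)
    if (!length(keep)) return(invisible(NULL))
    is_singl <- is.na(batch$family[keep])
    quota <- ifelse(is_singl,
                    cumsum(is_singl) <= n_singletons - n_singl_acc,
                    cumsum(!is_singl) <= n_family_target - n_fam_acc)
    keep <- keep[quota]
    if (!length(keep)) return(invisible(NULL))
    seen <<- c(seen, can[keep])
    n_singl_acc <<- n_singl_acc + sum(is.na(batch$family[keep]))
    n_fam_acc <<- n_fam_acc + sum(!is.na(batch$family[keep]))
    acc[[length(acc) + 1L]] <<- data.frame(smiles = can[keep],
                                           family = batch$family[keep],
                                           stringsAsFactors = FALSE)
    invisible(NULL)
  }

  while (n_fam_acc < n_family_target || n_singl_acc < n_singletons) {
    rounds <- rounds + 1L
    if (rounds > 200L)
      stop("infeasible spec: scaffold/substituent space exhausted after ",
           rounds - 1L, " rounds (", n_fam_acc + n_singl_acc, " of ",
           spec$n_total, " unique compliant structures)")
    need_fam <- n_family_target - n_fam_acc
    need_singl <- n_singletons - n_singl_acc
    # explore harder in later rounds, when most proposals are repeats
    boost <- 2 + rounds %/% 5

    rows <- list()
    if (spec$n_families > 0 && need_fam > 0) {
      # one complete chain per family per pass, families in random order,
      # until enough members are proposed to cover the remaining need
      proposed <- 0L
      budget <- ceiling(need_fam * 1.3) + 10L
      for (f in sample.int(spec$n_families)) {
        if (proposed >= budget) break
        chain <- family_chain(f)
        if (is.null(chain)) next
        rows[[length(rows) + 1L]] <- data.frame(
          smiles_raw = chain, family = sprintf("F%03d", f),
          stringsAsFactors = FALSE)
        proposed <- proposed + length(chain)
      }
      if (proposed == 0L)
        stop("infeasible spec: family decoration space exhausted (",
             n_fam_acc, " of ", n_family_target,
             " family members generated)")
    }
    if (need_singl > 0) {
      n_singl_round <- max(ceiling(need_singl * boost), 100L)
      for (k in seq_len(n_singl_round)) {
        fluor <- stats::runif(1) < spec$fluorination_rate
        rows[[length(rows) + 1L]] <- data.frame(
          smiles_raw = singleton_member(fluor),
          family = NA_character_, stringsAsFactors = FALSE)
      }
    }
    batch <- do.call(rbind, rows)
    fresh <- !vapply(batch$smiles_raw, function(s)
      exists(s, envir = seen_raw, inherits = FALSE), logical(1))
    for (s in batch$smiles_raw[fresh])
      assign(s, TRUE, envir = seen_raw)
    if (any(fresh)) accept_batch(batch[fresh, , drop = FALSE])
    if (isTRUE(getOption("fragdiv.fixture.verbose")))
      message(sprintf("round %d: fam %d/%d singl %d/%d (proposed %d, fresh %d)",
                      rounds, n_fam_acc, n_family_target, n_singl_acc,
                      n_singletons, nrow(batch), sum(fresh)))
  }

  all <- do.call(rbind, acc)
  # stable ids: family members numbered within family, singletons globally
  ids <- character(nrow(all))
  counters <- new.env(parent = emptyenv())
  n_s <- 0L
  for (i in seq_len(nrow(all))) {
    f <- all$family[i]
    if (is.na(f)) {
      n_s <- n_s + 1L
      ids[i] <- sprintf("S%05d", n_s)
    } else {
      cur <- (get0(f, envir = counters, ifnotfound = 0L)) + 1L
      assign(f, cur, envir = counters)
      ids[i] <- sprintf("%s_%02d", f, cur)
    }
  }
  col <- fragment_collection(all$smiles, id = ids,
                             provenance = sprintf("synthetic fixture (seed %d)",
                                                  spec$seed),
                             canonicalize = FALSE)
  attr(col, "families") <- stats::setNames(all$family, ids)
  attr(col, "fixture_spec") <- spec
  col
}

#' Redundancy summary of a fixture
#'
#' Verifies that the generated catalogue has the analog structure the
#' selection benchmarks rely on: within an analog family, a compound's
#' nearest neighbor should be markedly more similar than its nearest
#' neighbor outside the family.
#'
#' @param col a [generate_fixture()] collection (needs the `families`
#'   attribute).
#' @param fps optional precomputed [radial_fingerprints()] for `col`.
#' @return list with `within_family_nn` and `cross_family_nn` (mean maximum
#'   Tanimoto similarity within / outside the own family), `n_families`,
#'   and `flag` (`"ok"`, `"no families"`, or `"families indistinct"`).
#' @export
redundancy_check <- function(col, fps = NULL) {
  stopifnot(inherits(col, "fragment_collection"), nrow(col) >= 2)
  families <- attr(col, "families")
  if (is.null(families)) families <- stats::setNames(rep(NA_character_,
                                                         nrow(col)), col$id)
  if (is.null(fps)) fps <- radial_fingerprints(col)
  ix <- .fp_index(fps)
  fam_of <- families[names(fps)]
  has_fam <- !is.na(fam_of)
  fams <- unique(fam_of[has_fam])
  fams <- fams[vapply(fams, function(f) sum(fam_of == f, na.rm = TRUE) >= 2,
                      logical(1))]
  if (!length(fams))
    return(list(within_family_nn = NA_real_, cross_family_nn = NA_real_,
                n_families = 0L, flag = "no families"))
  within <- numeric(0); cross <- numeric(0)
  for (f in fams) {
    members <- which(!is.na(fam_of) & fam_of == f)
    others <- setdiff(seq_along(fps), members)
    within <- c(within, cpp_nn_max_sim(ix$sets[members]))
    if (length(others))
      cross <- c(cross, cpp_max_sim_to_set(ix$sets, as.integer(members),
                                           as.integer(others)))
  }
  w <- mean(within); x <- if (length(cross)) mean(cross) else NA_real_
  list(within_family_nn = w, cross_family_nn = x,
       n_families = length(fams),
       flag = if (!is.na(x) && x >= w) "families indistinct" else "ok")
}
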