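test_that("fingerprinting is deterministic and representation-independent", {
  col <- fragment_collection(c("CCO", "OCC", "Oc1ccccc1"))
  fps1 <- radial_fingerprints(col)
  fps2 <- radial_fingerprints(col)
  expect_identical(unclass(fps1)[[1]], unclass(fps2)[[1]])
  # ethanol written two ways yields the same feature set
  expect_identical(unclass(fps1)[[1]], unclass(fps1)[[2]])
  expect_false(identical(unclass(fps1)[[1]], unclass(fps1)[[3]]))
  # identifiers are 16-hex-digit 64-bit values
  expect_true(all(grepl("^[0-9a-f]{16}$", unlist(fps1))))
})

test_that("feature sets grow with iteration radius and molecule size", {
  col <- fragment_collection(c("C", "CC", "CCCCO"))
  f3 <- radial_fingerprints(col, n_iterations = 3)
  f0 <- radial_fingerprints(col, n_iterations = 0)
  expect_true(all(lengths(f3) >= lengths(f0)))
  expect_gte(length(f3[["M000002"]]), length(f3[["M000001"]]))
  # radius-0 environments can be suppressed
  nor0 <- radial_fingerprints(col, n_iterations = 3, emit_radius0 = FALSE)
  expect_true(all(lengths(nor0) < lengths(f3)))
})

test_that("equality decisions agree with an independent circular-fingerprint oracle", {
  smis <- panel_smiles()
  fps <- radial_fingerprints(fragment_collection(unname(smis), id = names(smis)))
  code <- paste0(
    "import json\n",
    "from rdkit import Chem\n",
    "from rdkit.Chem import rdFingerprintGenerator\n",
    "gen = rdFingerprintGenerator.GetMorganGenerator(radius=3)\n",
    "smis = json.loads('", jsonlite::toJSON(unname(smis)), "')\n",
    "fps = [sorted(gen.GetSparseCountFingerprint(Chem.MolFromSmiles(s))",
    ".GetNonzeroElements().keys()) for s in smis]\n",
    "print(json.dumps([[int(fps[i]==fps[j]) for j in range(len(fps))]",
    " for i in range(len(fps))]))\n")
  oracle <- rdkit_json(code)
  expect_false(is.null(oracle)) # the oracle toolkit must be present
  n <- length(smis)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    expect_equal(identical(unclass(fps)[[i]], unclass(fps)[[j]]),
                 oracle[i, j] == 1L,
                 info = sprintf("%s vs %s", names(smis)[i], names(smis)[j]))
  }
})

test_that("pooled_abundance does presence counting over molecules", {
  fps <- list(m1 = c("a", "b"), m2 = c("b", "c"))
  ab <- pooled_abundance(fps)
  expect_equal(as.integer(ab[c("a", "b", "c")]), c(1L, 2L, 1L))
  expect_equal(attr(ab, "total"), 4L)
  # one molecule / identical molecules
  expect_equal(attr(pooled_abundance(list(c("a", "b"))), "total"), 2L)
  expect_equal(as.integer(pooled_abundance(list(c("a", "b"), c("a", "b")))),
               c(2L, 2L))
  expect_error(pooled_abundance(list()), "empty")
  # total equals the sum of per-molecule distinct set sizes
  real <- small_fingerprints()
  expect_equal(attr(pooled_abundance(real), "total"), sum(lengths(real)))
})

test_that("tanimoto matches set arithmetic and its invariants", {
  expect_equal(tanimoto(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(tanimoto(c("a"), c("a")), 1.0)
  expect_equal(tanimoto(c("a"), c("b")), 0.0)
  expect_error(tanimoto(character(0), character(0)), "undefined")
  # property: symmetry and bounds over random sets
  set.seed(11)
  pool <- sprintf("f%03d", 1:60)
  for (k in 1:25) {
    a <- sample(pool, sample(1:20, 1))
    b <- sample(pool, sample(1:20, 1))
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(tanimoto(a, a), 1.0)
  }
})
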