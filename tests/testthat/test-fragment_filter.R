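test_that("computed descriptors match hand-checked reference values", {
  col <- fragment_collection(c("Oc1ccccc1", "C", "Oc1ccc2ccccc2c1", "CCCC",
                               "NC(=O)c1ccccc1"),
                             id = c("phenol", "methane", "naphthol",
                                    "butane", "benzamide"))
  pr <- compute_properties(col)
  expect_equal(pr$mw[1], 94.11, tolerance = 0.01)
  expect_equal(pr$n_rings, c(1L, 0L, 2L, 0L, 1L))
  expect_equal(pr$hbd[1], 1L)
  # methane: no donors, acceptors, rings or rotors
  expect_equal(unlist(pr[2, c("hbd", "hba", "rb", "n_rings")]),
               c(hbd = 0L, hba = 0L, rb = 0L, n_rings = 0L))
  # strict rotatable bonds: butane 1; benzamide 1 (amide C-N excluded)
  expect_equal(pr$rb[4], 1L)
  expect_equal(pr$rb[5], 1L)
  expect_true(all(pr$psa >= 0))
})

test_that("rule_of_3_filter retains exactly the compliant records", {
  col <- fragment_collection(c("Oc1ccccc1", "Oc1ccc2ccccc2c1"),
                             id = c("phenol", "naphthol"))
  out <- rule_of_3_filter(col)
  # phenol fails the MW floor (94.1 < 100); 2-naphthol passes every bound
  expect_equal(out$id, "naphthol")
  rej <- attr(out, "rejections")
  expect_equal(rej$id, "phenol")
  expect_match(rej$failed_rule, "mw")
  # empty rule set is the identity
  ident <- rule_of_3_filter(col, rules = default_rule_of_3()[0, ])
  expect_equal(ident$id, col$id)
})

test_that("filters are order-independent, idempotent and subset-valued", {
  col <- small_fixture()
  spiked <- fragment_collection(
    c(col$smiles[1:30],
      "CCCCCCCCCCCCCCCCCCCCCC(=O)OCCCCCC",  # MW and RB violations
      "CC(=O)Cl"),                           # acyl halide
    id = c(col$id[1:30], "big", "reactive"))
  a <- reactive_group_filter(rule_of_3_filter(spiked))
  b <- rule_of_3_filter(reactive_group_filter(spiked))
  expect_setequal(a$id, b$id)
  expect_false(any(c("big", "reactive") %in% a$id))
  expect_true(all(a$id %in% spiked$id))
  again <- rule_of_3_filter(a)
  expect_equal(again$id, a$id)
})

test_that("reactive_group_filter removes matches and reports patterns", {
  col <- fragment_collection(c("CC(=O)Cl", "c1ccccc1", "CC1CO1", "CCSC(C)=O"),
                             id = c("acyl", "benzene", "epox", "thioester"))
  out <- reactive_group_filter(col)
  expect_equal(out$id, "benzene")
  counts <- attr(out, "pattern_counts")
  expect_equal(unname(counts["acyl_halide"]), 1L)
  expect_equal(unname(counts["epoxide"]), 1L)
  # empty pattern set is the identity
  expect_equal(reactive_group_filter(col, patterns = character(0))$id, col$id)
  expect_error(reactive_group_filter(col, patterns = c(bad = "[[[")),
               "invalid SMARTS pattern 'bad'")
})

test_that("fluorine_filter keeps the 1-3 fluorine window", {
  col <- fragment_collection(c("Fc1ccccc1", "FC(F)(F)C(F)(F)F", "c1ccccc1"),
                             id = c("monoF", "hexaF", "noF"))
  out <- fluorine_filter(col, 1L, 3L)
  expect_equal(out$id, "monoF")
  expect_error(fluorine_filter(col, 3L, 1L), "min_f > max_f")
})
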