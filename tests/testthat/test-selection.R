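test_that("sphere exclusion honors the distance guarantee", {
  # synthetic feature sets with known pairwise geometry
  fps <- structure(list(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3"),
                        C = c("c1", "c2", "c3"), D = c("d1", "d2", "d3"),
                        E = c("e1", "e2", "e3")),
                   smiles = stats::setNames(paste0("s", 1:5), LETTERS[1:5]),
                   class = "fingerprint_set_list")
  # all pairwise distances are 1 >= 0.4: everything selected
  sel <- sphere_exclusion_select(fps, radius = 0.4)
  expect_setequal(sel$ordered_ids, LETTERS[1:5])
  aud <- audit_sphere_exclusion(fps, sel)
  expect_true(aud$separation_ok)
  expect_gte(aud$min_pairwise_distance, 0.4)

  # identical twins: exactly one of the pair survives
  twin <- structure(list(A = c("a", "b"), B = c("a", "b")),
                    smiles = stats::setNames(c("s1", "s2"), c("A", "B")),
                    class = "fingerprint_set_list")
  sel2 <- sphere_exclusion_select(twin, radius = 0.4)
  expect_length(sel2$ordered_ids, 1L)

  single <- twin[1]
  expect_length(sphere_exclusion_select(single, radius = 0.4)$ordered_ids, 1L)
  expect_error(sphere_exclusion_select(fps, radius = 1.5), "radius")
})

test_that("sphere exclusion separation and maximality hold on a real pool", {
  fps <- small_fingerprints()
  sel <- sphere_exclusion_select(fps, radius = 0.4)
  aud <- audit_sphere_exclusion(fps, sel)
  expect_true(aud$separation_ok)
  expect_true(aud$coverage_ok) # pool exhausted, so every leftover is covered
  # determinism: identical inputs give identical selections
  sel2 <- sphere_exclusion_select(fps, radius = 0.4)
  expect_identical(sel$ordered_ids, sel2$ordered_ids)
  # max_size truncation is a prefix of the full run
  selk <- sphere_exclusion_select(fps, radius = 0.4, max_size = 10)
  expect_identical(selk$ordered_ids, sel$ordered_ids[1:10])
})

test_that("random_select is seeded, uniform-without-replacement", {
  col <- small_fixture()
  r1 <- random_select(col, 50, seed = 9)
  r2 <- random_select(col, 50, seed = 9)
  expect_identical(r1$ordered_ids, r2$ordered_ids)
  expect_length(unique(r1$ordered_ids), 50L)
  r3 <- random_select(col, 50, seed = 10)
  expect_false(identical(r1$ordered_ids, r3$ordered_ids))
  # n = pool size is a permutation
  perm <- random_select(col, nrow(col), seed = 1)
  expect_setequal(perm$ordered_ids, col$id)
  expect_error(random_select(col, nrow(col) + 1, seed = 1), "pool size")
})

test_that("two-seed overlap matches the hypergeometric expectation", {
  ids <- sprintf("x%04d", 1:1000)
  overlaps <- vapply(1:6, function(s) {
    a <- random_select(ids, 100, seed = s)$ordered_ids
    b <- random_select(ids, 100, seed = s + 100)$ordered_ids
    length(intersect(a, b))
  }, numeric(1))
  # expected overlap n^2/N = 10; sd ~ 3, so the mean of 6 runs sits near 10
  expect_gt(mean(overlaps), 4)
  expect_lt(mean(overlaps), 16)
})

test_that("nested_prefixes gives nested ladder libraries", {
  res <- random_select(sprintf("m%02d", 1:40), 30, seed = 2)
  pre <- nested_prefixes(res, c(5, 10, 20))
  expect_named(pre, c("5", "10", "20"))
  expect_true(all(pre[["5"]] %in% pre[["10"]]))
  expect_true(all(pre[["10"]] %in% pre[["20"]]))
  expect_identical(pre[["20"]][1:5], pre[["5"]])
  expect_error(nested_prefixes(res, c(10, 35)), "exceeds")
  expect_error(nested_prefixes(res, c(10, 10)), "ascending")
})
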