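test_that("mean_nn_similarity matches brute-force cases", {
  # two identical compounds
  expect_equal(mean_nn_similarity(list(c("a", "b"), c("a", "b"))), 1.0)
  # three mutually disjoint sets
  expect_equal(mean_nn_similarity(list("a", "b", "c")), 0.0)
  # chain {a,b},{b,c},{c,d}: every NN similarity is 1/3
  expect_equal(mean_nn_similarity(list(c("a", "b"), c("b", "c"),
                                       c("c", "d"))), 1 / 3)
  expect_error(mean_nn_similarity(list(c("a"))), "size >= 2")
})

test_that("per-compound NN similarity never decreases as the library grows", {
  fps <- small_fingerprints()
  ix <- fragdiv:::.fp_index(fps)
  nn_small <- fragdiv:::cpp_nn_max_sim(ix$sets[1:40])
  nn_big <- fragdiv:::cpp_nn_max_sim(ix$sets[1:80])[1:40]
  expect_true(all(nn_big >= nn_small - 1e-12))
})

test_that("richness counts distinct features and is prefix-monotone", {
  expect_equal(richness(pooled_abundance(list(c("a")))), 1L)
  ab <- structure(c(a = 1L, b = 2L, c = 1L), total = 4L,
                  class = "feature_abundance")
  expect_equal(richness(ab), 3L)
  fps <- small_fingerprints()
  r <- vapply(c(10, 30, 60, 120), function(k)
    richness(pooled_abundance(fps[seq_len(k)])), numeric(1))
  expect_true(all(diff(r) >= 0))
  # merged library richness >= either sub-library (set-union oracle)
  r_ab <- richness(pooled_abundance(fps[1:60]))
  expect_gte(r_ab, richness(pooled_abundance(fps[1:30])))
  expect_gte(r_ab, richness(pooled_abundance(fps[31:60])))
})

test_that("true diversity equals the exponential of Shannon entropy", {
  # single feature
  expect_equal(true_diversity(pooled_abundance(list("a"))), 1.0)
  # uniform counts: D = R
  ab4 <- structure(rep(2L, 4), names = letters[1:4], total = 8L,
                   class = "feature_abundance")
  expect_equal(true_diversity(ab4), 4.0)
  # counts (2,1,1): D = 2^1.5
  ab3 <- structure(c(a = 2L, b = 1L, c = 1L), total = 4L,
                   class = "feature_abundance")
  expect_equal(true_diversity(ab3), 2^1.5, tolerance = 1e-12)
  expect_error(true_diversity(structure(integer(0),
                                        class = "feature_abundance")),
               "empty")
})

test_that("true diversity is bounded by richness and penalizes unevenness", {
  set.seed(21)
  for (k in 1:40) {
    counts <- sample(1:50, sample(2:30, 1), replace = TRUE)
    names(counts) <- paste0("f", seq_along(counts))
    D <- true_diversity(counts)
    expect_gte(D, 1 - 1e-9)
    expect_lte(D, length(counts) + 1e-9)
    # independent oracle: entropy by direct summation
    p <- counts / sum(counts)
    expect_lt(abs(D - exp(-sum(p * log(p)))), 1e-9)
    # transferring one count from a low to a high feature lowers D
    if (length(unique(counts)) > 1) {
      i <- which.min(counts); j <- which.max(counts)
      if (counts[i] > 1) {
        shifted <- counts; shifted[i] <- shifted[i] - 1L
        shifted[j] <- shifted[j] + 1L
        expect_lt(true_diversity(shifted), D)
      }
    }
  }
})

test_that("marginal_series computes interval slopes with sign behavior", {
  ms <- marginal_series(c(0, 100), c(0, 2890))
  expect_equal(ms$marginals, 28.9)
  expect_equal(marginal_series(c(1, 5, 9), c(3, 3, 3))$marginals, c(0, 0))
  declining <- marginal_series(c(100, 200), c(50, 40))
  expect_lt(declining$marginals, 0)
  expect_error(marginal_series(c(5, 2), c(1, 2)), "ascending")
  expect_error(marginal_series(c(1, 2), c(1)), "equally many")
})

test_that("evaluate_ladder reports per-size metrics and averages replicates", {
  col <- small_fixture()
  fps <- small_fingerprints()
  rnd <- lapply(1:3, function(s) random_select(col, 60, s))
  avg <- evaluate_ladder(fps, rnd, c(20, 40, 60))
  expect_equal(avg$size, c(20, 40, 60))
  expect_true(all(diff(avg$richness) >= 0))
  reps <- attr(avg, "replicates")
  expect_equal(nrow(reps), 9L)
  # the averaged value is the mean of the three replicates
  expect_equal(avg$richness[1],
               mean(reps$richness[reps$size == 20]))
  expect_error(evaluate_ladder(fps, rnd, c(1, 20)), ">= 2")
})
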