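# Model similarity matrices: cosine, semantic, phonological, family,
# encoder layers, second-order correlation, permutation-labeling test.

test_that("cosine similarity matches direct micro-oracles and validates input", {
  m <- cosine_similarity_matrix(rbind(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(m$values["a", "b"], 1.0)

  m <- cosine_similarity_matrix(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(m$values["a", "b"], 0.0)

  m <- cosine_similarity_matrix(rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0)))
  expect_equal(m$values["a", "b"], 0.5)      # 1 / (sqrt(2) * sqrt(2))

  expect_error(cosine_similarity_matrix(rbind(a = c(1, 1), zz = c(0, 0))),
               "zz")
  expect_error(cosine_similarity_matrix(list(a = c(1, 2), b = c(1, 2, 3))),
               "length")
})

test_that("semantic similarity equals brute-force pairwise cosine and obeys range", {
  expect_equal(semantic_similarity_matrix(matrix(1, 1, 2,
                                                 dimnames = list("x", NULL)))$values,
               matrix(1, 1, 1, dimnames = list("x", "x")))

  disjoint <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(semantic_similarity_matrix(disjoint)$values["a", "b"], 0)

  set.seed(42)
  cfm <- matrix(rbinom(12, 1, 0.6), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  cfm[rowSums(cfm) == 0, 1] <- 1
  sm <- semantic_similarity_matrix(cfm)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(sm$values[i, j], bf_cosine(cfm[i, ], cfm[j, ]), tolerance = 1e-12)
  }
  expect_true(all(sm$values >= 0 & sm$values <= 1))
  expect_error(semantic_similarity_matrix(rbind(a = c(1, 0), b = c(0, 0))),
               "no applicable feature")
})

test_that("phonological similarity is length-normalized edit similarity", {
  m <- phonological_similarity_matrix(c(x = "kata", y = "kata"))
  expect_equal(m$values["x", "y"], 1)
  m <- phonological_similarity_matrix(c(x = "abc", y = "xyz"))
  expect_equal(m$values["x", "y"], 0)
  m <- phonological_similarity_matrix(c(x = "bas", y = "bal"))
  expect_equal(m$values["x", "y"], 1 - 1/3)   # one substitution over length 3
  expect_error(phonological_similarity_matrix(c(x = "ab", y = "")), "empty")
})

test_that("edit distance matches brute-force recursion, is symmetric, and satisfies the triangle inequality", {
  set.seed(7)
  alphabet <- c("a", "b", "c")
  strs <- replicate(12, paste(sample(alphabet, sample(1:6, 1), replace = TRUE),
                              collapse = ""))
  d <- utils::adist(strs, strs)
  for (i in 1:12) for (j in 1:12) {
    if (i < j) expect_identical(d[i, j], d[j, i])
    if (i < j) expect_equal(unname(d[i, j]), bf_levenshtein(strs[i], strs[j]))
  }
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    expect_lte(d[i, k], d[i, j] + d[j, k])
  }
})

test_that("family similarity is a binary block matrix", {
  fam <- setNames(rep("f1", 4), paste0("g", 1:4))
  expect_true(all(family_similarity_matrix(fam)$values == 1))

  fam <- setNames(rep(paste0("f", 1:8), each = 3), paste0("g", 1:24))
  m <- family_similarity_matrix(fam)
  expect_equal(dim(m$values), c(24L, 24L))
  off_ones <- rowSums(m$values) - 1          # diagonal removed
  expect_true(all(off_ones == 2))            # 2 other members per family of 3

  fam <- setNames(paste0("f", 1:5), paste0("g", 1:5))
  expect_equal(family_similarity_matrix(fam)$values, diag(5),
               ignore_attr = TRUE)
})

test_that("layer similarity matrices preserve order and equal the semantic construction on identical input", {
  set.seed(3)
  cfm <- matrix(rbinom(24, 1, 0.5), 4, 6,
                dimnames = list(paste0("s", 1:4), NULL))
  cfm[rowSums(cfm) == 0, 1] <- 1
  layers <- list(L1 = cfm,
                 L2 = matrix(rnorm(24), 4, dimnames = list(paste0("s", 1:4), NULL)))
  out <- layer_similarity_matrices(layers)
  expect_named(out, c("L1", "L2"))
  expect_equal(out$L1$values, semantic_similarity_matrix(cfm)$values)
  expect_equal(out$L2$meta$layer, "L2")

  dup <- layers$L2; dup[2, ] <- dup[1, ]
  out2 <- layer_similarity_matrices(list(A = dup))
  expect_equal(out2$A$values[1, 2], 1.0)

  eight <- setNames(rep(list(layers$L2), 8), paste0("layer", 1:8))
  expect_length(layer_similarity_matrices(eight), 8L)
})

test_that("matrix_correlation is upper-triangle Spearman with midranks", {
  set.seed(11)
  p <- matrix(rnorm(4 * 5), 4, dimnames = list(letters[1:4], NULL))
  a <- cosine_similarity_matrix(p)
  expect_equal(matrix_correlation(a, a), 1.0)

  # reverse the upper-triangle order -> perfect anti-correlation
  v <- a$values[upper.tri(a$values)]
  bvals <- a$values
  bvals[upper.tri(bvals)] <- -v
  bvals <- t(bvals); bvals[upper.tri(bvals)] <- -v; diag(bvals) <- 1
  b <- similarity_matrix(t(bvals), a$labels)
  expect_equal(matrix_correlation(a, b), -1.0)

  q <- matrix(rnorm(4 * 5), 4, dimnames = list(letters[1:4], NULL))
  b2 <- cosine_similarity_matrix(q)
  expect_equal(matrix_correlation(a, b2), bf_spearman_upper(a$values, b2$values),
               tolerance = 1e-12)

  b3 <- cosine_similarity_matrix(q[c(2, 1, 3, 4), ])
  expect_error(matrix_correlation(a, b3), "label mismatch")

  # invariant to a common relabeling of both matrices
  perm <- c(3, 1, 4, 2)
  ap <- similarity_matrix(a$values[perm, perm], a$labels[perm])
  bp <- similarity_matrix(b2$values[perm, perm], b2$labels[perm])
  expect_equal(matrix_correlation(ap, bp), matrix_correlation(a, b2),
               tolerance = 1e-12)
})

test_that("matrix_permutation_test: maximal statistic, determinism, estimator form", {
  set.seed(2)
  # 10 labels: the chance of drawing the identity relabeling (which ties the
  # maximal statistic) in 99 draws is ~3e-5, so p = 1/100 is the stable outcome
  p <- matrix(rnorm(10 * 8), 10, dimnames = list(letters[1:10], NULL))
  a <- cosine_similarity_matrix(p)
  res <- matrix_permutation_test(a, a, n_perm = 99, seed = 4)
  expect_equal(res$observed, 1.0)
  expect_equal(res$p, 1 / 100)               # nothing beats rho = 1
  expect_equal(res$n_perm, 99L)

  res2 <- matrix_permutation_test(a, a, n_perm = 99, seed = 4)
  expect_identical(res$null, res2$null)
  res3 <- matrix_permutation_test(a, a, n_perm = 99, seed = 5)
  expect_false(identical(res$null, res3$null))

  expect_error(matrix_permutation_test(a, a, n_perm = 0), "n_perm")
  expect_equal(matrix_permutation_test(a, a, n_perm = 49, seed = 1,
                                       n_comparisons = 8)$corrected_alpha,
               0.05 / 8)
})

test_that("permutation p-values are calibrated under exchangeable nulls", {
  # 1,000 independent null pairs (24 labels), 200 permutations each:
  # rejection at 0.05 must land in [0.03, 0.07].
  n_sim <- 1000L
  rej <- logical(n_sim)
  set.seed(2024)
  for (i in seq_len(n_sim)) {
    a <- cosine_similarity_matrix(
      matrix(rnorm(24 * 20), 24, dimnames = list(sprintf("e%02d", 1:24), NULL)))
    b <- cosine_similarity_matrix(
      matrix(rnorm(24 * 20), 24, dimnames = list(sprintf("e%02d", 1:24), NULL)))
    rej[i] <- matrix_permutation_test(a, b, n_perm = 200, seed = i)$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("similarity_matrix invariants are enforced on construction", {
  expect_error(similarity_matrix(matrix(c(1, 0.5, 0.4, 1), 2),
                                 c("a", "b")), "symmetric")
  expect_error(similarity_matrix(matrix(c(1, 2, 2, 1), 2), c("a", "b")),
               "outside")
  expect_error(similarity_matrix(diag(2), c("a", "a")), "duplicate")
})
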