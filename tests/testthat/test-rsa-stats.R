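# Pair-exclusion statistics, permutation nulls, subject ranks, and
# rank-based comparisons, checked against naive double-loop oracles.

test_that("fmri_similarity_matrix equals the brute-force double loop exactly", {
  tt <- fixture_tiny_tt()
  rps <- fixture_rps(tt, n_voxels = 7, seed = 31)
  m <- fmri_similarity_matrix(rps)
  expect_equal(m$values, bf_fmri_matrix(rps$values, tt), tolerance = 1e-12)

  # all trials identical -> all off-diagonal cells 1
  rps1 <- response_patterns(matrix(1, 6, 4) * rep(1, 6), tt)
  m1 <- fmri_similarity_matrix(rps1)
  expect_true(all(abs(m1$values - 1) < 1e-12))

  # entity pair with no admissible (different-location) pair errors by name
  tt_bad <- trial_table(data.frame(
    subject = "s1", run = rep(1:2, each = 2),
    onset = rep(c(2, 10.5), 2),
    entity = rep(c("e1", "e2"), 2),
    location = c(1L, 1L, 1L, 1L)))
  rps_bad <- fixture_rps(tt_bad, n_voxels = 4, seed = 1)
  expect_error(fmri_similarity_matrix(rps_bad), "e1.*e2")
})

test_that("group_average_matrix is the element-wise mean", {
  tt <- fixture_tiny_tt()
  ms <- lapply(1:5, function(s) fmri_similarity_matrix(fixture_rps(tt, 6, s)))
  g <- group_average_matrix(ms)
  manual <- Reduce(`+`, lapply(ms, function(m) m$values)) / 5
  expect_equal(g$values, manual, tolerance = 1e-12)
  expect_equal(group_average_matrix(ms[1])$values, ms[[1]]$values)

  ms2 <- ms
  ms2[[2]] <- similarity_matrix(ms[[2]]$values,
                                labels = c("e1", "e2", "zz"))
  expect_error(group_average_matrix(ms2), "label mismatch")
})

test_that("identity and location statistics match their brute-force oracles", {
  tt <- fixture_tiny_tt()
  rps_list <- lapply(1:3, function(s) {
    tts <- fixture_tiny_tt(subject = sprintf("s%d", s))
    fixture_rps(tts, n_voxels = 7, seed = 100 + s)
  })
  id <- identity_statistic(rps_list, n_perm = 120, seed = 9)
  loc <- location_statistic(rps_list, n_perm = 120, seed = 9)

  bf_id <- mean(sapply(rps_list, function(r) bf_identity_subject(r$values, r$trials)))
  bf_loc <- mean(sapply(rps_list, function(r) bf_location_subject(r$values, r$trials)))
  expect_equal(id$observed, bf_id, tolerance = 1e-12)
  expect_equal(loc$observed, bf_loc, tolerance = 1e-12)

  # determinism and the p-value estimator contract
  id2 <- identity_statistic(rps_list, n_perm = 120, seed = 9)
  expect_identical(id$null, id2$null)
  expect_equal(id$p, (1 + sum(id$null >= id$observed)) / 121)
  expect_equal(dim(id$per_subject$nulls), c(120L, 3L))

  # identical patterns -> identity CS = 1
  same <- lapply(1:2, function(s) {
    tts <- fixture_tiny_tt(subject = sprintf("s%d", s))
    response_patterns(matrix(rep(c(1, 2, 3, 4), each = 6), 6), tts)
  })
  expect_equal(identity_statistic(same, n_perm = 1, seed = 1)$observed, 1.0)
})

test_that("the same-location exclusion is what shields identity from location signal", {
  # Pure location signal, zero entity signal, and entities partially
  # *confounded* with location (each entity has a home quadrant it occupies
  # in 6 of its 8 trials — the situation the exclusion exists for). With the
  # exclusion the identity statistic sits at chance; without it, same-entity
  # same-location pairs leak the location similarity in and the statistic
  # turns significantly positive. The pair of assertions pins the rule.
  set.seed(77)
  n_sub <- 6
  make_confounded_tt <- function(sub) {
    home <- ((0:5) %% 4) + 1L
    rows <- do.call(rbind, lapply(1:8, function(r) {
      loc <- if (r <= 6) home else ((home + r - 7L) %% 4L) + 1L
      data.frame(subject = sub, run = r, onset = 2 + 8.5 * (0:5),
                 entity = paste0("e", 1:6), location = loc)
    }))
    trial_table(rows)
  }
  rps_list <- lapply(seq_len(n_sub), function(s) {
    tts <- make_confounded_tt(sprintf("s%d", s))
    loc_pat <- matrix(rnorm(4 * 40), 4)
    vals <- loc_pat[tts$location, ] + 0.3 * matrix(rnorm(nrow(tts) * 40), nrow(tts))
    response_patterns(vals, tts)
  })
  with_excl <- identity_statistic(rps_list, n_perm = 200, seed = 5)
  without_excl <- identity_statistic(rps_list, n_perm = 200, seed = 5,
                                     exclude_same_location = FALSE)
  expect_gt(with_excl$p, 0.01)               # at chance
  expect_lt(abs(with_excl$observed), 0.1)
  expect_lt(without_excl$p, 0.01)            # confound leaks in
  expect_gt(without_excl$observed, 0.1)
})

test_that("entity/location role swap in the generator swaps which statistic fires", {
  base <- list(n_subjects = 4, n_runs = 4, n_entities = 6, n_locations = 4,
               n_voxels = 120, noise_sd = 0.8, seed = 41)
  cfg_ent <- do.call(generator_config,
                     c(base, list(semantic_gain = 0, identity_gain = 1.2,
                                  location_gain = 0)))
  cfg_loc <- do.call(generator_config,
                     c(base, list(semantic_gain = 0, identity_gain = 0,
                                  location_gain = 1.2)))
  an_ent <- analyze_dataset(generate_dataset(cfg_ent),
                            statistics = c("identity", "location"),
                            n_perm = 200, seed = 42)
  an_loc <- analyze_dataset(generate_dataset(cfg_loc),
                            statistics = c("identity", "location"),
                            n_perm = 200, seed = 42)
  expect_lt(an_ent$identity$p, 0.05)
  expect_gt(an_ent$location$p, 0.05)
  expect_lt(an_loc$location$p, 0.05)
  expect_gt(an_loc$identity$p, 0.05)
})

test_that("rsa_test: maximal statistic and per-subject variant", {
  set.seed(12)
  p <- matrix(rnorm(10 * 9), 10, dimnames = list(paste0("e", 1:10), NULL))
  model <- cosine_similarity_matrix(p)
  res <- rsa_test(model, model, n_perm = 99, seed = 2)
  expect_equal(res$observed, 1.0)
  expect_equal(res$p, 1 / 100)
  expect_error(rsa_test(model, model, n_perm = 0), "n_perm")

  tt <- fixture_tiny_tt()
  mats <- lapply(1:4, function(s) fmri_similarity_matrix(fixture_rps(tt, 6, s)))
  model3 <- cosine_similarity_matrix(
    matrix(rnorm(3 * 5), 3, dimnames = list(c("e1", "e2", "e3"), NULL)))
  st <- rsa_subject_tests(mats, model3, n_perm = 150, seed = 6)
  expect_length(st$observed, 4L)
  expect_equal(dim(st$nulls), c(150L, 4L))
  expect_equal(st$p[1],
               (1 + sum(st$nulls[, 1] >= st$observed[1])) / 151,
               ignore_attr = TRUE)
})

test_that("subject_rank percentiles follow the estimator", {
  nulls <- matrix(seq_len(999), 999, 1)
  expect_equal(subject_rank(c(s1 = 1000), nulls)$rank, 1.0)
  expect_equal(subject_rank(c(s1 = 0), nulls)$rank, 1 / 1000)
  expect_equal(subject_rank(c(s1 = 500), nulls)$rank, 501 / 1000)
  expect_error(subject_rank(c(s1 = 1), matrix(1:50, 50, 1)), "100")
})

test_that("compare_conditions: exact signed-rank, degenerate case, Mann-Whitney", {
  # 10 uniformly ordered pairs, one-tailed exact: p = 1/2^10
  a <- seq(0.2, 0.9, length.out = 10)
  b <- a - seq(0.01, 0.1, length.out = 10)
  cmp <- compare_conditions(a, b, paired = TRUE, tail = "one")
  expect_equal(cmp$p, 1 / 1024, tolerance = 1e-12)
  expect_equal(cmp$p, bf_signed_rank_p(a - b), tolerance = 1e-12)

  # random-sign case against the enumeration oracle
  set.seed(19)
  d <- rnorm(8)
  b8 <- b[1:8]
  cmp2 <- compare_conditions(b8 + d, b8, paired = TRUE, tail = "one")
  expect_equal(cmp2$p, bf_signed_rank_p(d), tolerance = 1e-12)

  expect_equal(compare_conditions(a, a, paired = TRUE)$p, 1)

  u <- compare_conditions(c(0.1, 0.4, 0.7, 0.2), c(0.3, 0.5, 0.6, 0.8),
                          paired = FALSE)
  expect_equal(u$method, "mann_whitney_u")
  expect_gt(u$p, 0.05)
})

test_that("subjectwise diagnostics: Z transform and degenerate guards", {
  set.seed(23)
  rho <- rnorm(31, mean = 0.1, sd = 0.05)
  pv <- runif(31, 0.01, 0.99)
  d <- subjectwise_diagnostics(rho, pv)
  expect_equal(d$z, qnorm(1 - pv))
  pv2 <- pv; pv2[1] <- 0.0228
  expect_equal(subjectwise_diagnostics(rho, pv2)$z[1], 2.0, tolerance = 0.001)

  expect_error(subjectwise_diagnostics(rep(0.5, 5), runif(5)), "constant")
  expect_error(subjectwise_diagnostics(rho, rep(0.5, 31)), "constant")
  expect_error(subjectwise_diagnostics(rho[1:2], pv[1:2]), "3 subjects")
})

test_that("Shapiro-Wilk diagnostic is calibrated on normal draws", {
  set.seed(99)
  rej <- replicate(1000, shapiro.test(rnorm(31))$p.value < 0.05)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("category restriction confines the statistic to that category's trials", {
  tt <- fixture_tiny_tt()           # e1,e3 instruments; e2 vehicles
  rps <- fixture_rps(tt, n_voxels = 6, seed = 55)
  res <- identity_statistic(list(rps), n_perm = 10, seed = 1,
                            restrict_to_category = "instruments")
  sub_rows <- tt$category == "instruments"
  tts <- tt[sub_rows, , drop = FALSE]; class(tts) <- class(tt)
  bf <- bf_identity_subject(rps$values[sub_rows, ], tts)
  expect_equal(res$observed, bf, tolerance = 1e-12)
})
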