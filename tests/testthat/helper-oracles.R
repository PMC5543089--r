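# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no shared cosine/rank helpers): plain double loops and
# textbook formulas only.

bf_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# Unit-cost Levenshtein distance by plain recursion (strings <= 6 symbols).
bf_levenshtein <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  rest_a <- substr(a, 2, nchar(a))
  rest_b <- substr(b, 2, nchar(b))
  min(bf_levenshtein(rest_a, b) + 1L,
      bf_levenshtein(a, rest_b) + 1L,
      bf_levenshtein(rest_a, rest_b) + cost)
}

# Spearman over strictly-upper-triangle cells: rank both, then the textbook
# Pearson formula.
bf_spearman_upper <- function(A, B) {
  x <- rank(A[upper.tri(A)])
  y <- rank(B[upper.tri(B)])
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Entity x entity matrix with same-location exclusion, naive quadruple loop.
bf_fmri_matrix <- function(values, tt) {
  ents <- sort(unique(tt$entity))
  n <- length(ents)
  out <- diag(1, n); dimnames(out) <- list(ents, ents)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    acc <- c()
    for (a in which(tt$entity == ents[i])) for (b in which(tt$entity == ents[j])) {
      if (tt$location[a] != tt$location[b]) {
        acc <- c(acc, bf_cosine(values[a, ], values[b, ]))
      }
    }
    out[i, j] <- mean(acc)
  }
  out
}

# Per-subject identity statistic: per entity, mean cosine over same-entity
# pairs at different locations; then mean over entities.
bf_identity_subject <- function(values, tt) {
  ents <- unique(tt$entity)
  per_ent <- sapply(ents, function(e) {
    rows <- which(tt$entity == e)
    acc <- c()
    for (ii in seq_along(rows)) for (jj in seq_along(rows)) {
      if (ii < jj && tt$location[rows[ii]] != tt$location[rows[jj]]) {
        acc <- c(acc, bf_cosine(values[rows[ii], ], values[rows[jj], ]))
      }
    }
    mean(acc)
  })
  mean(per_ent)
}

# Mirror image: per location, same-location different-entity pairs.
bf_location_subject <- function(values, tt) {
  locs <- unique(tt$location)
  per_loc <- sapply(locs, function(l) {
    rows <- which(tt$location == l)
    acc <- c()
    for (ii in seq_along(rows)) for (jj in seq_along(rows)) {
      if (ii < jj && tt$entity[rows[ii]] != tt$entity[rows[jj]]) {
        acc <- c(acc, bf_cosine(values[rows[ii], ], values[rows[jj], ]))
      }
    }
    mean(acc)
  })
  mean(per_loc)
}

# Exact one-tailed signed-rank p by enumerating all 2^n sign assignments.
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

# Six-trial fixture: 3 entities x 2 runs, two locations used so that every
# entity pair has admissible cross-location pairs, every entity has
# different-location repeats, and every used location holds >= 2 entities.
fixture_tiny_tt <- function(subject = "s1") {
  trial_table(data.frame(
    subject = subject,
    run = rep(1:2, each = 3),
    onset = rep(c(2, 10.5, 19), 2),
    entity = rep(c("e1", "e2", "e3"), 2),
    category = rep(c("instruments", "vehicles", "instruments"), 2),
    location = c(1L, 2L, 1L, 2L, 1L, 2L),
    size = 1L, mirrored = FALSE
  ))
}

fixture_rps <- function(tt, n_voxels = 8, seed = 1) {
  set.seed(seed)
  response_patterns(matrix(rnorm(nrow(tt) * n_voxels), nrow(tt)), tt)
}

# Full-design trial table (counterbalanced) pulled from the generator with
# minimal signal content.
fixture_design_tt <- function(n_subjects = 1, n_runs = 12, n_entities = 24,
                              n_locations = 4, seed = 5) {
  cfg <- generator_config(n_subjects = n_subjects, n_runs = n_runs,
                          n_entities = n_entities, n_locations = n_locations,
                          n_voxels = 2, semantic_gain = 0, noise_sd = 1,
                          temporal_noise_sd = 0, seed = seed)
  generate_dataset(cfg)$trials
}
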