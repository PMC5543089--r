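# Pattern-similarity statistics with pair exclusion and permutation-labeling
# inference: the semantic (second-order RSA), object-identity, and location
# statistics, plus subject ranking and rank-based secondary comparisons.

# Trial x trial cosine similarity of response patterns.
trial_cosine_matrix <- function(rps) {
  stopifnot(inherits(rps, "response_patterns"))
  v <- rps$values
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm == 0
  if (any(zero)) {
    stopf("zero-norm response pattern at trial row(s): %s",
          paste(which(zero), collapse = ", "))
  }
  u <- v / nrm
  tcrossprod(u)
}

#' Entity-by-entity fMRI similarity matrix with same-location exclusion
#'
#' For every pair of entities (i, j), the cell is the mean cosine similarity
#' over all pairs of trials (one trial of i, one of j) whose stimuli appeared
#' at *different* screen locations. Excluding same-location trial pairs
#' maximizes the contribution of location-invariant object representations.
#' The diagonal is set to 1 by convention and never used downstream
#' (within-entity similarity is the business of [identity_statistic()]).
#'
#' An alternative cell definition — cosine between per-entity average
#' patterns, under which the location exclusion is not expressible — is
#' available via `cell = "entity_average"` for sensitivity analysis.
#'
#' @param rps A `response_patterns` for one subject.
#' @param exclude_same_location Apply the same-location pair exclusion
#'   (default TRUE).
#' @param cell Cell definition: `"trial_pairs"` (default) or
#'   `"entity_average"`.
#' @return A `similarity_matrix` over entities (sorted label order), with
#'   attribute-like `meta$n_pairs`: the admissible pair count per cell.
#' @export
fmri_similarity_matrix <- function(rps, exclude_same_location = TRUE,
                                   cell = c("trial_pairs", "entity_average")) {
  cell <- match.arg(cell)
  stopifnot(inherits(rps, "response_patterns"))
  tt <- rps$trials
  entities <- sort(unique(tt$entity))
  if (length(entities) < 2L) stopf("need at least 2 entities")
  if (cell == "entity_average") {
    avg <- average_patterns(rps, "entity")
    out <- cosine_similarity_matrix(avg, meta = list(source = "fmri",
                                                     cell = "entity_average"))
    return(out)
  }
  C <- trial_cosine_matrix(rps)
  n <- length(entities)
  rows_of <- lapply(entities, function(e) which(tt$entity == e))
  vals <- diag(1, n)
  n_pairs <- matrix(0L, n, n, dimnames = list(entities, entities))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ri <- rows_of[[i]]; rj <- rows_of[[j]]
      keep <- if (exclude_same_location) {
        outer(tt$location[ri], tt$location[rj], `!=`)
      } else {
        matrix(TRUE, length(ri), length(rj))
      }
      if (!any(keep)) {
        stopf("no admissible trial pair for entities '%s' and '%s'",
              entities[i], entities[j])
      }
      vals[i, j] <- vals[j, i] <- mean(C[ri, rj, drop = FALSE][keep])
      n_pairs[i, j] <- n_pairs[j, i] <- sum(keep)
    }
  }
  similarity_matrix(vals, entities,
                    meta = list(source = "fmri", cell = "trial_pairs",
                                exclude_same_location = exclude_same_location,
                                n_pairs = n_pairs))
}

#' Element-wise group average of per-subject similarity matrices
#'
#' @param matrices List of `similarity_matrix` objects with identical labels.
#' @return A `similarity_matrix`; `meta$n_subjects` records the group size.
#' @export
group_average_matrix <- function(matrices) {
  if (length(matrices) < 1L) stopf("empty matrix list")
  for (m in matrices[-1]) check_same_labels(matrices[[1]], m)
  vals <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  similarity_matrix(vals, matrices[[1]]$labels,
                    meta = list(source = "fmri_group_average",
                                n_subjects = length(matrices)))
}

#' Second-order RSA test of a group fMRI matrix against a model matrix
#'
#' Spearman correlation between the group-averaged fMRI similarity matrix and
#' a model similarity matrix over strictly-upper-triangle cells, tested
#' one-tailed (greater than chance) against permutation labelings of the
#' model matrix.
#'
#' @param group_matrix Group-averaged fMRI `similarity_matrix`.
#' @param model Model `similarity_matrix`, same label order.
#' @param n_perm Number of permutation labelings (default 10000).
#' @param seed Integer seed.
#' @param n_comparisons Bonferroni family size for the reported threshold.
#' @return A `perm_result` with statistic `"rsa_spearman"`.
#' @export
rsa_test <- function(group_matrix, model, n_perm = 10000, seed = 1L,
                     n_comparisons = 1L) {
  res <- matrix_permutation_test(group_matrix, model, n_perm = n_perm,
                                 seed = seed, n_comparisons = n_comparisons)
  res$statistic <- "rsa_spearman"
  res
}

#' Per-subject RSA tests against a model matrix
#'
#' Runs [rsa_test()] for each subject's matrix with seeds derived from one
#' master seed; the per-subject rho, p and null samples feed
#' [subject_rank()] and [subjectwise_diagnostics()].
#'
#' @param subject_matrices Named list of per-subject `similarity_matrix`.
#' @param model Model `similarity_matrix`.
#' @param n_perm,seed As in [rsa_test()].
#' @return List with `observed` (named rho vector), `p` (named vector), and
#'   `nulls` (n_perm x n_subjects matrix).
#' @export
rsa_subject_tests <- function(subject_matrices, model, n_perm = 10000, seed = 1L) {
  ns <- length(subject_matrices)
  if (ns < 1L) stopf("no subject matrices")
  seeds <- split_seed(seed, ns)
  nms <- names(subject_matrices) %||% paste0("sub", seq_len(ns))
  nulls <- matrix(NA_real_, n_perm, ns, dimnames = list(NULL, nms))
  observed <- p <- stats::setNames(numeric(ns), nms)
  for (s in seq_len(ns)) {
    r <- rsa_test(subject_matrices[[s]], model, n_perm = n_perm, seed = seeds[s])
    observed[s] <- r$observed; p[s] <- r$p; nulls[, s] <- r$null
  }
  list(observed = observed, p = p, nulls = nulls, seed = seed)
}

# Mean cosine over admissible pairs, grouped by a label: for each level of
# `grp` (entity for the identity statistic, location for the location
# statistic), average C over within-level trial pairs whose `other` label
# differs, then average over levels. `strict` errors on a level with no
# admissible pair (observed data); the null path drops such levels instead.
#
# Vectorized via indicator algebra: with Z the trial x level membership
# indicator and M = C * D (D the symmetric admissibility mask, zero
# diagonal), the per-level pair sum is diag(Z' M Z) / 2 and the pair count
# diag(Z' D Z) / 2, so one permutation costs two small matrix products.
grouped_pair_mean <- function(C, grp, other, exclude_other = TRUE,
                              strict = TRUE) {
  pm <- pair_mean_engine(C, other, exclude_other)
  pm(grp, strict = strict)
}

# Returns a closure evaluating the grouped pair mean for any label
# assignment over fixed C and `other`; precomputes the admissibility mask so
# permutation loops only pay for the two matrix products.
pair_mean_engine <- function(C, other, exclude_other = TRUE) {
  n <- nrow(C)
  D <- if (exclude_other) outer(other, other, `!=`) * 1 else
    matrix(1, n, n)
  diag(D) <- 0
  M <- C * D
  function(grp, strict = TRUE) {
    levels_ <- unique(grp)
    Z <- outer(grp, levels_, `==`) * 1
    counts <- colSums(Z * (D %*% Z))          # 2x the admissible pair count
    if (strict) {
      sizes <- colSums(Z)
      if (any(sizes < 2)) {
        stopf("level '%s' has fewer than 2 trials", levels_[sizes < 2][1])
      }
      if (any(counts == 0)) {
        stopf("no admissible trial pair within level '%s'",
              levels_[counts == 0][1])
      }
    }
    ok <- counts > 0
    if (!any(ok)) {
      # only reachable under permuted labelings of degenerate designs; the
      # null sample is undefined and dropped from the null distribution
      return(NA_real_)
    }
    sums <- colSums(Z * (M %*% Z))
    mean(sums[ok] / counts[ok])
  }
}

# Admissible within-level pair counts (diagnostic / contract checking).
grouped_pair_counts <- function(tt, group_by = "entity",
                                other = if (group_by == "entity") "location" else "entity") {
  grp <- as.character(tt[[group_by]])
  oth <- tt[[other]]
  vapply(stats::setNames(unique(grp), unique(grp)), function(g) {
    rows <- which(grp == g)
    keep <- upper.tri(matrix(0, length(rows), length(rows))) &
      outer(oth[rows], oth[rows], `!=`)
    sum(keep)
  }, integer(1))
}

# Shared engine for the identity and location statistics: `group_by` labels
# are the ones permuted under the null; `other` labels define the exclusion
# and stay fixed.
paired_cosine_statistic <- function(rps_list, group_by, other, statistic,
                                    n_perm, seed, restrict_to_category = NULL,
                                    exclude_other = TRUE) {
  if (inherits(rps_list, "response_patterns")) rps_list <- list(rps_list)
  ns <- length(rps_list)
  if (ns < 1L) stopf("no subjects supplied")
  if (!is.numeric(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  seeds <- split_seed(seed, ns)
  subjects <- vapply(rps_list, function(r) r$trials$subject[1], character(1))
  obs <- stats::setNames(numeric(ns), subjects)
  nulls <- matrix(NA_real_, n_perm, ns, dimnames = list(NULL, subjects))
  n_pairs <- vector("list", ns)
  for (s in seq_len(ns)) {
    rps <- rps_list[[s]]
    tt <- rps$trials
    keep_rows <- if (is.null(restrict_to_category)) seq_len(nrow(tt)) else
      which(tt$category == restrict_to_category)
    if (length(keep_rows) < 2L) stopf("fewer than 2 trials after category restriction")
    C <- trial_cosine_matrix(rps)[keep_rows, keep_rows, drop = FALSE]
    grp <- as.character(tt[[group_by]])[keep_rows]
    oth <- tt[[other]][keep_rows]
    pm <- pair_mean_engine(C, oth, exclude_other = exclude_other)
    obs[s] <- pm(grp, strict = TRUE)
    n_pairs[[s]] <- grouped_pair_counts(tt[keep_rows, , drop = FALSE],
                                        group_by, other)
    nulls[, s] <- with_seed(seeds[s], {
      n_tr <- length(grp)
      vapply(seq_len(n_perm), function(k) {
        pm(grp[sample.int(n_tr)], strict = FALSE)
      }, numeric(1))
    })
  }
  perm_result(
    statistic = statistic,
    observed = mean(obs),
    null = rowMeans(nulls),
    seed = seed,
    tail = "upper",
    per_subject = list(observed = obs, nulls = nulls, subjects = subjects),
    extra = list(n_pairs = n_pairs,
                 restrict_to_category = restrict_to_category)
  )
}

#' Location-invariant object-identity statistic
#'
#' Mean cosine similarity between pairs of trials showing the *same entity*,
#' excluding pairs that also share the stimulus location (so the statistic
#' cannot be driven by retinotopic overlap). Per subject the mean is taken
#' within each entity, then over entities; the group observed value is the
#' mean across subjects. The null permutes entity labels across trials within
#' each subject independently per iteration (locations fixed, exclusion
#' re-applied); the group null sample is the across-subject mean of that
#' iteration. Per-subject null distributions are retained for
#' [subject_rank()].
#'
#' @param rps_list A `response_patterns` or list of them (one per subject).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer master seed (split per subject).
#' @param restrict_to_category Optional category label to confine the
#'   analysis to.
#' @param exclude_same_location Test-only switch for the exclusion rule
#'   (default TRUE; switching it off is only meaningful for validating the
#'   exclusion logic).
#' @return A `perm_result` with statistic `"object_identity_cosine"`.
#' @export
identity_statistic <- function(rps_list, n_perm = 10000, seed = 1L,
                               restrict_to_category = NULL,
                               exclude_same_location = TRUE) {
  paired_cosine_statistic(rps_list, group_by = "entity", other = "location",
                          statistic = "object_identity_cosine",
                          n_perm = n_perm, seed = seed,
                          restrict_to_category = restrict_to_category,
                          exclude_other = exclude_same_location)
}

#' Object-invariant location statistic
#'
#' Mirror image of [identity_statistic()]: mean cosine similarity between
#' pairs of trials sharing the *stimulus location*, excluding pairs that also
#' share the entity (so object identity cannot drive it). The null permutes
#' location labels across trials within each subject (entities fixed), with
#' the same-entity-same-location exclusion applied in the observed and every
#' null computation alike.
#'
#' @inheritParams identity_statistic
#' @param exclude_same_entity Test-only switch for the exclusion rule.
#' @return A `perm_result` with statistic `"location_cosine"`.
#' @export
location_statistic <- function(rps_list, n_perm = 10000, seed = 1L,
                               restrict_to_category = NULL,
                               exclude_same_entity = TRUE) {
  paired_cosine_statistic(rps_list, group_by = "location", other = "entity",
                          statistic = "location_cosine",
                          n_perm = n_perm, seed = seed,
                          restrict_to_category = restrict_to_category,
                          exclude_other = exclude_same_entity)
}

#' Rank of each subject's observed statistic within their own null
#'
#' Percentile `(1 + #\{null <= observed\}) / (n_perm + 1)`, in (0, 1]. These
#' subject-specific ranks are the inputs to the rank-based comparisons
#' between regions, categories or groups.
#'
#' @param observed Named numeric vector of per-subject observed statistics.
#' @param nulls n_perm x n_subjects matrix of null samples (>= 100 rows),
#'   columns aligned with `observed`.
#' @return Data frame with columns `subject` and `rank`.
#' @export
subject_rank <- function(observed, nulls) {
  nulls <- as.matrix(nulls)
  if (nrow(nulls) < 100L) stopf("need at least 100 null samples per subject")
  if (ncol(nulls) != length(observed)) stopf("null columns do not match subjects")
  n_perm <- nrow(nulls)
  r <- vapply(seq_along(observed), function(s) {
    ns <- nulls[!is.na(nulls[, s]), s]
    (1 + sum(ns <= observed[s])) / (length(ns) + 1)
  }, numeric(1))
  data.frame(subject = names(observed) %||% paste0("sub", seq_along(observed)),
             rank = r, row.names = NULL)
}

#' Rank-based comparison between conditions, regions or groups
#'
#' Paired samples (same subjects in two regions, or two categories within
#' subject): Wilcoxon signed-rank on the within-subject rank differences,
#' with the requested tail ("one" tests a > b). Unpaired groups (e.g.,
#' mirrored vs non-mirrored subjects): two-tailed Mann-Whitney U. Exact null
#' distributions are used for n <= 25 when there are no ties or zero
#' differences; otherwise the normal approximation with continuity
#' correction. Zero differences are dropped (Wilcoxon convention); if all
#' differences are zero the samples are identical and p = 1 is returned.
#'
#' @param ranks_a,ranks_b Numeric vectors of subject ranks (aligned when
#'   paired).
#' @param paired Logical.
#' @param tail `"one"` (a greater than b) or `"two"`.
#' @return List with `p`, `statistic`, and `method`.
#' @export
compare_conditions <- function(ranks_a, ranks_b, paired = TRUE,
                               tail = c("two", "one")) {
  tail <- match.arg(tail)
  ranks_a <- as.numeric(ranks_a); ranks_b <- as.numeric(ranks_b)
  if (paired) {
    if (length(ranks_a) != length(ranks_b)) stopf("paired samples differ in length")
    d <- ranks_a - ranks_b
    if (all(d == 0)) {
      return(list(p = 1, statistic = NA_real_,
                  method = "wilcoxon_signed_rank (degenerate: all differences zero)"))
    }
    nz <- d[d != 0]
    exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
    ht <- suppressWarnings(stats::wilcox.test(
      ranks_a, ranks_b, paired = TRUE,
      alternative = if (tail == "one") "greater" else "two.sided",
      exact = exact, correct = TRUE
    ))
    list(p = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "wilcoxon_signed_rank")
  } else {
    n <- length(ranks_a) + length(ranks_b)
    ties <- any(duplicated(c(ranks_a, ranks_b)))
    ht <- suppressWarnings(stats::wilcox.test(
      ranks_a, ranks_b, paired = FALSE, alternative = "two.sided",
      exact = n <= 50L && !ties, correct = TRUE
    ))
    list(p = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "mann_whitney_u")
  }
}

#' Across-subject normality and location diagnostics
#'
#' For the distribution of per-subject second-order correlations: Shapiro-Wilk
#' normality p-value and a one-tailed one-sample t-test against zero. The
#' per-subject permutation p-values are additionally transformed to standard
#' normal quantiles, `Z_i = qnorm(1 - p_i)`, and the same pair of tests is
#' applied to the Z scores.
#'
#' @param per_subject_rho Numeric vector of per-subject correlations (n >= 3,
#'   non-constant).
#' @param per_subject_p Numeric vector of per-subject permutation p-values in
#'   (0, 1\], same length.
#' @return List with `shapiro_p_rho`, `t_rho`, `t_p_rho`, `z`, `shapiro_p_z`,
#'   `t_z`, `t_p_z`.
#' @export
subjectwise_diagnostics <- function(per_subject_rho, per_subject_p) {
  rho <- as.numeric(per_subject_rho); pv <- as.numeric(per_subject_p)
  if (length(rho) < 3L) stopf("need at least 3 subjects")
  if (length(pv) != length(rho)) stopf("rho and p vectors differ in length")
  if (stats::sd(rho) == 0) stopf("degenerate case: per-subject correlations are constant")
  if (any(pv <= 0 | pv > 1)) stopf("p-values must lie in (0, 1]")
  z <- stats::qnorm(1 - pv)
  t_rho <- stats::t.test(rho, mu = 0, alternative = "greater")
  if (stats::sd(z) == 0) stopf("degenerate case: Z scores are constant")
  t_z <- stats::t.test(z, mu = 0, alternative = "greater")
  list(
    shapiro_p_rho = unname(stats::shapiro.test(rho)$p.value),
    t_rho = unname(t_rho$statistic), t_p_rho = unname(t_rho$p.value),
    z = z,
    shapiro_p_z = unname(stats::shapiro.test(z)$p.value),
    t_z = unname(t_z$statistic), t_p_z = unname(t_z$p.value)
  )
}
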