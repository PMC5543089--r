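#' Labeled similarity matrices
#'
#' A `similarity_matrix` is a square symmetric matrix of pairwise similarities
#' between labeled conditions (entities, stimuli, ...). It is the common
#' currency of the package: model matrices (semantic, phonological, shape
#' family, encoder layers) and fMRI pattern matrices are all of this class, so
#' second-order (representational) comparisons apply uniformly.
#'
#' Invariants enforced on construction: unique labels; symmetry within 1e-10;
#' values in \[-1, 1\]; unit diagonal wherever the source vector is nonzero.
#'
#' @param values Numeric n x n matrix.
#' @param labels Character vector of n unique labels.
#' @param meta Named list recording provenance (source kind, parameters).
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels = rownames(values), meta = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("similarity matrix must be square")
  if (is.null(labels)) stopf("labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stopf("label count does not match matrix size")
  if (anyDuplicated(labels)) {
    stopf("duplicate labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stopf("similarity values must be finite")
  if (max(abs(values - t(values))) > 1e-10) {
    stopf("matrix is not symmetric within 1e-10")
  }
  values <- clamp_unit(values)
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  structure(
    list(labels = labels, values = values, meta = meta),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d labels, source: %s\n",
              length(x$labels), x$meta$source %||% "unspecified"))
  n <- min(6L, length(x$labels))
  print(round(x$values[seq_len(n), seq_len(n), drop = FALSE], 4))
  if (length(x$labels) > n) cat(sprintf("... %d more labels\n", length(x$labels) - n))
  invisible(x)
}

#' @export
dim.similarity_matrix <- function(x) dim(x$values)

#' Cosine similarity matrix of labeled vectors
#'
#' Computes cos(v_i, v_j) = <v_i, v_j> / (|v_i| |v_j|) for every pair of rows.
#'
#' @param vectors Numeric matrix with one labeled row per item (rownames are
#'   the labels), or a named list of equal-length numeric vectors.
#' @param meta Optional provenance list merged into the result's `meta`.
#' @return A `similarity_matrix` with unit diagonal.
#' @export
cosine_similarity_matrix <- function(vectors, meta = list()) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    len <- lengths(vectors)
    if (length(unique(len)) > 1L) stopf("vectors differ in length")
    vectors <- do.call(rbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) stopf("vectors must carry labels as rownames")
  if (nrow(vectors) < 2L) stopf("need at least 2 labeled vectors")
  nrm <- sqrt(rowSums(vectors^2))
  zero <- nrm == 0
  if (any(zero)) {
    stopf("zero-norm vector for label(s): %s",
          paste(rownames(vectors)[zero], collapse = ", "))
  }
  unit <- vectors / nrm
  vals <- tcrossprod(unit)
  diag(vals) <- 1
  similarity_matrix(vals, rownames(vectors),
                    meta = c(list(source = meta$source %||% "cosine"), meta))
}

#' Semantic similarity matrix from a concept-feature matrix
#'
#' Feature-norm semantics: each entity is a row of feature applicability
#' weights (binary in classic feature-generation norms); semantic similarity
#' between two entities is the cosine of their feature rows. With non-negative
#' weights all similarities lie in \[0, 1\].
#'
#' @param cfm Entity x feature numeric matrix, rownames = entity labels,
#'   colnames = feature labels; non-negative, no all-zero row.
#' @return A `similarity_matrix` with `meta$source = "semantic"`.
#' @export
semantic_similarity_matrix <- function(cfm) {
  cfm <- as.matrix(cfm)
  if (is.null(rownames(cfm))) stopf("concept-feature matrix needs entity rownames")
  if (anyDuplicated(rownames(cfm))) stopf("duplicate entity labels")
  if (any(cfm < 0)) stopf("feature weights must be non-negative")
  empty <- rowSums(cfm != 0) == 0
  if (any(empty)) {
    stopf("entity with no applicable feature: %s",
          paste(rownames(cfm)[empty], collapse = ", "))
  }
  if (nrow(cfm) == 1L) {
    return(similarity_matrix(matrix(1, 1, 1), rownames(cfm),
                             meta = list(source = "semantic")))
  }
  cosine_similarity_matrix(cfm, meta = list(source = "semantic",
                                            n_features = ncol(cfm)))
}

#' Phonological similarity matrix from transcriptions
#'
#' Normalized edit similarity between phonetic transcriptions:
#' `1 - L(s_i, s_j) / max(|s_i|, |s_j|)` with L the unit-cost Levenshtein
#' distance over code points. Normalizing by the longer string keeps values in
#' \[0, 1\]; identical strings score 1.
#'
#' @param transcriptions Named character vector, names = item labels, values =
#'   transcriptions (one symbol per code point).
#' @return A `similarity_matrix` with `meta$source = "phonological"`.
#' @export
phonological_similarity_matrix <- function(transcriptions) {
  if (is.null(names(transcriptions))) stopf("transcriptions must be named")
  s <- as.character(transcriptions)
  labels <- names(transcriptions)
  if (anyDuplicated(labels)) stopf("duplicate labels")
  if (any(is.na(s) | nchar(s) == 0)) {
    stopf("empty transcription for label(s): %s",
          paste(labels[is.na(s) | nchar(s) == 0], collapse = ", "))
  }
  d <- utils::adist(s, s)                       # unit-cost Levenshtein
  len <- nchar(s, type = "chars")
  denom <- outer(len, len, pmax)
  vals <- 1 - d / denom
  diag(vals) <- 1
  similarity_matrix(vals, labels, meta = list(source = "phonological"))
}

#' Binary family-structure similarity matrix
#'
#' Block-structural similarity for stimuli organized in families (e.g.,
#' parameterized artificial shapes built as sets of related variants):
#' 1 if two stimuli share a family, 0 otherwise.
#'
#' @param family_labels Named vector; names = stimulus labels, values =
#'   family identifiers.
#' @return A binary `similarity_matrix` with unit diagonal.
#' @export
family_similarity_matrix <- function(family_labels) {
  if (is.null(names(family_labels))) stopf("family labels must be named")
  labels <- names(family_labels)
  if (anyDuplicated(labels)) stopf("duplicate stimulus labels")
  fam <- as.character(family_labels)
  if (length(fam) < 1L) stopf("need at least one family")
  vals <- outer(fam, fam, `==`) * 1
  diag(vals) <- 1
  similarity_matrix(vals, labels,
                    meta = list(source = "family",
                                n_families = length(unique(fam))))
}

#' Per-layer cosine similarity matrices from encoder activations
#'
#' Given per-stimulus activation vectors from each layer of an external
#' encoder (e.g., a deep convolutional network), returns one cosine
#' similarity matrix per layer, in layer order.
#'
#' @param layers Named list of numeric matrices, one per layer, each with one
#'   labeled row per stimulus (identical rownames across layers).
#' @return List of `similarity_matrix` objects; each carries its layer name in
#'   `meta$layer`.
#' @export
layer_similarity_matrices <- function(layers) {
  if (!is.list(layers) || length(layers) < 1L) stopf("need at least one layer")
  nms <- names(layers) %||% paste0("layer", seq_along(layers))
  ref <- rownames(as.matrix(layers[[1]]))
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    m <- as.matrix(layers[[i]])
    if (!identical(rownames(m), ref)) {
      stopf("layer '%s': stimulus labels differ from first layer", nms[i])
    }
    out[[i]] <- tryCatch(
      cosine_similarity_matrix(m, meta = list(source = "encoder_layer",
                                              layer = nms[i])),
      error = function(e) stopf("layer '%s': %s", nms[i], conditionMessage(e))
    )
  }
  names(out) <- nms
  out
}

#' Second-order (representational) rank correlation
#'
#' Spearman correlation between two similarity matrices over their strictly
#' upper-triangle cells only — the diagonal and the redundant lower triangle
#' are excluded. Ties get midranks.
#'
#' @param a,b `similarity_matrix` objects with identical labels in identical
#'   order, n >= 3.
#' @return Rank correlation coefficient in \[-1, 1\].
#' @export
matrix_correlation <- function(a, b) {
  check_same_labels(a, b)
  if (length(a$labels) < 3L) stopf("need at least 3 labels")
  ut <- upper.tri(a$values)
  stats::cor(a$values[ut], b$values[ut], method = "spearman")
}

check_same_labels <- function(a, b) {
  stopifnot(inherits(a, "similarity_matrix"), inherits(b, "similarity_matrix"))
  if (!identical(a$labels, b$labels)) {
    diff <- union(setdiff(a$labels, b$labels), setdiff(b$labels, a$labels))
    if (length(diff) == 0) diff <- "(same set, different order)"
    stopf("label mismatch between matrices: %s", paste(diff, collapse = ", "))
  }
  invisible(TRUE)
}

# Fast Spearman over upper triangles against a pre-ranked reference vector;
# used inside permutation loops.
spearman_vs_ranked <- function(rank_a, b_vals, ut) {
  stats::cor(rank_a, rank(b_vals[ut]))
}

#' Permutation-labeling test for second-order correlation
#'
#' Tests whether the rank correlation between two similarity matrices exceeds
#' chance. The null distribution relabels the conditions of `b`: each
#' permutation jointly reorders rows and columns by a uniform random
#' permutation (an entity-relabeling null that preserves symmetry), and the
#' upper-triangle Spearman correlation with `a` is recomputed. One-tailed
#' (upper) p-value `(1 + #\{null >= observed\}) / (n_perm + 1)`, which is
#' strictly positive and valid at finite `n_perm`.
#'
#' @param a,b `similarity_matrix` objects, identical label order.
#' @param n_perm Number of permutation labelings (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical nulls.
#' @param n_comparisons Bonferroni family size; the corrected threshold
#'   `0.05 / n_comparisons` is reported alongside.
#' @return A `perm_result` (observed rho, null samples, p, seed, tail).
#' @export
matrix_permutation_test <- function(a, b, n_perm = 10000, seed = 1L,
                                    n_comparisons = 1L) {
  check_same_labels(a, b)
  if (length(a$labels) < 3L) stopf("need at least 3 labels")
  if (!is.numeric(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  n <- length(a$labels)
  ut <- upper.tri(a$values)
  rank_a <- rank(a$values[ut])
  observed <- stats::cor(rank_a, rank(b$values[ut]))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      spearman_vs_ranked(rank_a, b$values[p, p], ut)
    }, numeric(1))
  })
  perm_result(
    statistic = "second_order_spearman",
    observed = observed,
    null = null,
    seed = seed,
    tail = "upper",
    extra = list(n_comparisons = n_comparisons,
                 corrected_alpha = 0.05 / n_comparisons)
  )
}
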