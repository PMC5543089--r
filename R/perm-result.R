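#' Permutation test result
#'
#' Container for an observed statistic (rank correlation rho or mean cosine
#' similarity CS), its permutation-labeling null samples, and the one-tailed
#' p-value `(1 + #\{null >= observed\}) / (n_perm + 1)` for the upper tail
#' (mirrored for the lower tail).
#'
#' @param statistic Name of the statistic.
#' @param observed Observed value.
#' @param null Numeric vector of null samples (length `n_perm`).
#' @param seed Seed that generated the null.
#' @param tail "upper" or "lower".
#' @param per_subject Optional list with per-subject observed values and null
#'   samples (n_perm x n_subjects matrix), kept for subject ranking.
#' @param extra Optional named list of additional metadata.
#' @return An object of class `perm_result`.
#' @export
perm_result <- function(statistic, observed, null, seed,
                        tail = c("upper", "lower"),
                        per_subject = NULL, extra = list()) {
  tail <- match.arg(tail)
  nn <- null[!is.na(null)]           # undefined (degenerate) samples dropped
  n_perm <- length(nn)
  if (n_perm < 1L) stopf("null sample vector is empty")
  exceed <- if (tail == "upper") sum(nn >= observed) else sum(nn <= observed)
  p <- (1 + exceed) / (n_perm + 1)
  structure(
    c(list(statistic = statistic, observed = observed, null = null,
           p = p, n_perm = n_perm, seed = seed, tail = tail,
           per_subject = per_subject), extra),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s\n  observed = %.6g, p = %.6g (%s tail, %d permutations, seed %s)\n",
              x$statistic, x$observed, x$p, x$tail, x$n_perm,
              format(x$seed)))
  if (!is.null(x$per_subject)) {
    cat(sprintf("  per-subject values retained for %d subjects\n",
                length(x$per_subject$observed)))
  }
  invisible(x)
}

#' Serialize a permutation result to JSON
#'
#' Writes the scalar record (statistic, observed, p, n_perm, seed, tail) as
#' JSON; optionally the null samples as a one-column CSV next to it.
#'
#' @param x A `perm_result`.
#' @param path Output JSON path.
#' @param null_csv Optional path for the null samples.
#' @return `path`, invisibly.
#' @export
write_perm_result <- function(x, path, null_csv = NULL) {
  stopifnot(inherits(x, "perm_result"))
  rec <- list(statistic = x$statistic, observed = x$observed, p = x$p,
              n_perm = x$n_perm, seed = x$seed, tail = x$tail)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_csv)) {
    utils::write.csv(data.frame(null = x$null), null_csv, row.names = FALSE)
  }
  invisible(path)
}
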