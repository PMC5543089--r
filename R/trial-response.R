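#' Voxel time series for one run
#'
#' @param values Time x voxel numeric matrix (rows are scans).
#' @param tr Sampling interval (repetition time) in seconds, > 0.
#' @param run Run identifier.
#' @param voxel_ids Optional voxel identifiers aligned to a mask (default
#'   sequential).
#' @return An object of class `voxel_timeseries`.
#' @export
voxel_timeseries <- function(values, tr, run = 1L, voxel_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stopf("TR must be > 0")
  if (nrow(values) < 2L) stopf("need at least 2 time points")
  if (any(!is.finite(values))) stopf("time series contains non-finite values")
  structure(
    list(values = values, tr = as.numeric(tr), run = run,
         voxel_ids = voxel_ids %||% seq_len(ncol(values))),
    class = "voxel_timeseries"
  )
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("<voxel_timeseries> run %s: %d scans x %d voxels, TR %.3g s\n",
              format(x$run), nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

# Discrete cosine drift basis (DCT-II, constant term excluded). The number of
# regressors is floor(2 * duration / cutoff), the usual high-pass
# parameterization: the slowest retained-out frequency is 1/cutoff Hz.
dct_basis <- function(n_scans, tr, cutoff) {
  k_max <- floor(2 * n_scans * tr / cutoff)
  if (k_max < 1L) return(matrix(numeric(0), n_scans, 0))
  t_idx <- seq_len(n_scans) - 1L
  vapply(seq_len(k_max), function(k) {
    cos(pi * (2 * t_idx + 1) * k / (2 * n_scans))
  }, numeric(n_scans))
}

#' Remove nuisance signals and low-frequency drift
#'
#' Per voxel, fits ordinary least squares on
#' \[intercept | nuisance regressors | discrete-cosine drift basis up to the
#' high-pass cutoff\] and returns the residuals. Residuals are orthogonal to
#' the design, and the operation is idempotent.
#'
#' @param ts A `voxel_timeseries`.
#' @param regressors Optional time x k numeric matrix (e.g., motion
#'   parameters); rows must match the number of scans.
#' @param highpass_cutoff High-pass cutoff period in seconds (default 128);
#'   must exceed `2 * TR`. `Inf` disables drift regressors.
#' @return A `voxel_timeseries` of residuals.
#' @export
nuisance_regress <- function(ts, regressors = NULL, highpass_cutoff = 128) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  n <- nrow(ts$values)
  if (!is.infinite(highpass_cutoff) && highpass_cutoff <= 2 * ts$tr) {
    stopf("highpass_cutoff must exceed 2*TR = %.3g s", 2 * ts$tr)
  }
  X <- cbind(intercept = rep(1, n))
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != n) stopf("regressor rows (%d) != scans (%d)",
                                     nrow(regressors), n)
    colnames(regressors) <- colnames(regressors) %||%
      paste0("nuisance", seq_len(ncol(regressors)))
    X <- cbind(X, regressors)
  }
  if (!is.infinite(highpass_cutoff)) {
    drift <- dct_basis(n, ts$tr, highpass_cutoff)
    if (ncol(drift) > 0) {
      colnames(drift) <- paste0("dct", seq_len(ncol(drift)))
      X <- cbind(X, drift)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient nuisance design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  res <- ts$values - X %*% qr.coef(qrX, ts$values)
  voxel_timeseries(res, tr = ts$tr, run = ts$run, voxel_ids = ts$voxel_ids)
}

# Per-trial frame weights realizing "linearly interpolate onto a peristimulus
# grid, then trapezoid-integrate": both steps are linear in the data, so each
# trial reduces to one weight vector over scans and the whole run to one
# matrix product.
integral_weights <- function(n_scans, tr, onsets, window, substep) {
  grid_rel <- seq(window[1], window[2], by = substep)
  if (abs(grid_rel[length(grid_rel)] - window[2]) > 1e-9) {
    stopf("substep must divide the window width")
  }
  m <- length(grid_rel)
  quad <- rep(substep, m); quad[c(1, m)] <- substep / 2   # trapezoid rule
  t_max <- (n_scans - 1) * tr
  W <- matrix(0, length(onsets), n_scans)
  for (i in seq_along(onsets)) {
    g <- onsets[i] + grid_rel
    if (g[m] > t_max + 1e-9 || g[1] < -1e-9) {
      stopf("trial %d (onset %.3f s): window [%.3f, %.3f] s exceeds run duration %.3f s",
            i, onsets[i], g[1], g[m], t_max)
    }
    idx <- pmin(pmax(floor(g / tr) + 1L, 1L), n_scans - 1L)
    frac <- g / tr - (idx - 1L)
    acc <- rowsum(c(quad * (1 - frac), quad * frac), c(idx, idx + 1L))
    W[i, as.integer(rownames(acc))] <- acc
  }
  W
}

#' Per-trial BOLD response integrals
#'
#' For each trial onset and each voxel, computes the area under the BOLD
#' curve in a post-stimulus window (default 2-8 s): the time series is
#' linearly interpolated onto a peristimulus grid at `substep` resolution and
#' integrated by the trapezoidal rule. Units are signal x seconds. No
#' baseline is subtracted; drift removal is assumed done upstream.
#'
#' @param ts A `voxel_timeseries` for one run.
#' @param onsets Trial onsets in seconds from run start.
#' @param window Integration window (start, end) seconds post-onset.
#' @param substep Peristimulus grid step in seconds (<= TR; default 0.1).
#' @return Trial x voxel matrix of integral values.
#' @export
bold_integral <- function(ts, onsets, window = c(2, 8), substep = 0.1) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  if (length(window) != 2L || window[1] >= window[2]) {
    stopf("window must be (start, end) with start < end")
  }
  if (substep > ts$tr + 1e-12) stopf("substep must not exceed TR")
  W <- integral_weights(nrow(ts$values), ts$tr, onsets, window, substep)
  W %*% ts$values
}

#' Extract aligned response patterns for a full session
#'
#' Applies `bold_integral` run by run and stacks the results into a
#' `response_patterns` object aligned row-for-row with the trial table.
#'
#' @param ts_list List of `voxel_timeseries`, one per run, named or ordered by
#'   run id.
#' @param tt A `trial_table` for one subject.
#' @param window,substep Passed to `bold_integral`.
#' @return A `response_patterns` object: `values` (trial x voxel matrix, rows
#'   aligned to `tt`), `trials` (the table), `window`.
#' @export
extract_patterns <- function(ts_list, tt, window = c(2, 8), substep = 0.1) {
  stopifnot(inherits(tt, "trial_table"))
  if (length(unique(tt$subject)) != 1L) {
    stopf("extract_patterns expects a single subject's trial table")
  }
  runs <- sort(unique(tt$run))
  ts_runs <- vapply(ts_list, function(ts) as.integer(ts$run), integer(1))
  out <- NULL
  for (r in runs) {
    ts <- ts_list[[match(r, ts_runs)]]
    if (is.na(match(r, ts_runs))) stopf("no time series supplied for run %d", r)
    rows <- which(tt$run == r)
    vals <- bold_integral(ts, tt$onset[rows], window = window, substep = substep)
    if (is.null(out)) out <- matrix(NA_real_, nrow(tt), ncol(vals))
    out[rows, ] <- vals
  }
  response_patterns(out, tt, window = window)
}

#' Trial-by-voxel response pattern set
#'
#' @param values Trial x voxel matrix of BOLD integrals (signal x seconds),
#'   rows aligned with `trials`.
#' @param trials The `trial_table` the rows align to.
#' @param window Integration window used.
#' @return An object of class `response_patterns`.
#' @export
response_patterns <- function(values, trials, window = c(2, 8)) {
  values <- as.matrix(values)
  stopifnot(inherits(trials, "trial_table"))
  if (nrow(values) != nrow(trials)) {
    stopf("pattern rows (%d) do not align with trial table rows (%d)",
          nrow(values), nrow(trials))
  }
  if (window[1] >= window[2]) stopf("window start must precede end")
  structure(list(values = values, trials = trials, window = window),
            class = "response_patterns")
}

#' @export
print.response_patterns <- function(x, ...) {
  cat(sprintf("<response_patterns> %d trials x %d voxels, window [%g, %g] s\n",
              nrow(x$values), ncol(x$values), x$window[1], x$window[2]))
  invisible(x)
}

#' Average response patterns by a design factor
#'
#' Arithmetic mean of trial vectors per level of a design column (typically
#' `entity`), yielding the per-condition "response pattern".
#'
#' @param rps A `response_patterns`.
#' @param group_by Name of a `trial_table` column.
#' @return Level x voxel matrix; attribute `n_trials` gives group sizes.
#' @export
average_patterns <- function(rps, group_by = "entity") {
  stopifnot(inherits(rps, "response_patterns"))
  g <- rps$trials[[group_by]]
  if (is.null(g)) stopf("unknown design field '%s'", group_by)
  g <- as.character(g)
  counts <- table(g)
  if (any(counts == 0)) stopf("empty group in '%s'", group_by)
  sums <- rowsum(rps$values, g)                 # sorted by level
  out <- sums / as.vector(counts[rownames(sums)])
  attr(out, "n_trials") <- as.integer(counts[rownames(sums)])
  out
}
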