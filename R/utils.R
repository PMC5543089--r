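# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so seeded operations never perturb
#' user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds from a master seed; all randomness in the package flows
# through these so serial and per-component execution agree. Kept below 2^31.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Clamp numerical cosine overshoot (|x| <= 1 + eps from rounding) back to
# [-1, 1]; anything beyond tol is a real error upstream.
clamp_unit <- function(x, tol = 1e-8) {
  bad <- abs(x) > 1 + tol
  if (any(bad, na.rm = TRUE)) {
    stop("similarity values outside [-1, 1] beyond numerical tolerance",
         call. = FALSE)
  }
  pmin(pmax(x, -1), 1)
}

# Mean of upper-triangle values selected by a logical mask; NA when empty.
upper_tri_mean <- function(m, mask) {
  sel <- mask & upper.tri(m)
  if (!any(sel)) return(NA_real_)
  mean(m[sel])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
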