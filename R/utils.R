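# Internal helpers shared across modules.

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores the global `.Random.seed` so seeded internals never
#' perturb the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a named sub-stream seed from a master seed
#'
#' A single pipeline seed fans out to per-module streams so that, e.g., the
#' SPD bootstrap seed never perturbs phase-representative selection.
#' Kept below 2^31 - 1 (R integers are 32-bit).
#' @param seed master seed (integer)
#' @param stream stream name (character)
#' @return an integer seed
#' @export
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729 + 17) %% 2147483629L)
}

# run-length spans of a logical vector; returns matrix of (start_idx, end_idx)
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# pointwise empirical quantile envelope over replicate rows (matrix n_rep x n_grid)
envelope_quantiles <- function(reps, coverage) {
  alpha <- (1 - coverage) / 2
  lo <- apply(reps, 2, stats::quantile, probs = alpha, na.rm = TRUE, names = FALSE)
  hi <- apply(reps, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE, names = FALSE)
  list(lower = lo, upper = hi)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single proportion in [0, 1]", name), call. = FALSE)
}
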