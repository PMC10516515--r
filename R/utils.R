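# Internal helpers shared across modules.

#' Signal a covleak error condition
#'
#' All package errors carry the class `covleak_error` plus a specific
#' subclass (`disclosure_refused`, `unknown_variable`, `length_mismatch`,
#' `shape_mismatch`, `degenerate_probe`, `singular_probe`, `probe_degenerate`,
#' `budget_exhausted`, `invalid_parameter`, `spec_invalid`, `format_error`,
#' `incomplete_target`) so callers can branch with `tryCatch()`.
#'
#' @noRd
fl_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "covleak_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a 32-bit-safe sub-seed from a base seed and an index.
sub_seed <- function(seed, index) {
  (abs(as.numeric(seed)) * 7919 + 104729 * as.numeric(index)) %% 2147483629
}

#' Draws from the Laplace (double-exponential) distribution
#'
#' Location 0. The Laplace distribution with scale `b` has variance `2 b^2`;
#' it is the noise distribution of the classical epsilon-differential-privacy
#' Laplace mechanism.
#'
#' @param n number of draws.
#' @param scale scale parameter `b > 0`.
#' @return numeric vector of `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' var(rlaplace(1e4, scale = 2)) # close to 2 * 2^2 = 8
rlaplace <- function(n, scale = 1) {
  if (!is.numeric(scale) || scale <= 0) {
    fl_stop("invalid_parameter", "Laplace scale must be > 0, got %s", format(scale))
  }
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

# Laplace CDF, used by tests for distributional checks.
plaplace <- function(q, scale = 1) {
  ifelse(q < 0, 0.5 * exp(q / scale), 1 - 0.5 * exp(-q / scale))
}

#' Reconstruction error metrics
#'
#' @param truth true data vector.
#' @param estimate reconstructed vector of the same length.
#' @return list with `max_abs_error`, `rel_mse` (mean squared error divided by
#'   the sample variance of `truth`, denominator n-1) and `pearson_r`.
#' @export
reconstruction_metrics <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  err <- estimate - truth
  list(
    max_abs_error = max(abs(err)),
    rel_mse = mean(err^2) / stats::var(truth),
    pearson_r = stats::cor(truth, estimate)
  )
}
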