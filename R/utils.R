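#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile runif setNames plogis qlogis uniroot
#' @importFrom utils read.csv write.csv
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Normalize a categorical marginal
#'
#' Printed probability rows are renormalized to sum to one while preserving
#' ratios. A warning is emitted when the raw sum deviates from 1 by more than
#' `warn_tol` (printed tables occasionally sum to e.g. 101% or 121%).
#'
#' @param p named numeric vector of non-negative class probabilities.
#' @param what label used in warnings/errors.
#' @param warn_tol deviation of the raw sum from 1 that triggers a warning.
#' @return `p` rescaled to sum to exactly 1.
#' @export
normalize_marginal <- function(p, what = "marginal", warn_tol = 0.005) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("invalid %s: entries must be finite and non-negative", what))
  }
  s <- sum(p)
  if (s <= 0) stop(sprintf("invalid %s: all classes have zero probability", what))
  if (abs(s - 1) > warn_tol) {
    warning(sprintf("%s sums to %.4f; renormalizing to 1", what, s))
  }
  p / s
}

#' Largest-remainder apportionment of n units to classes
#'
#' Deterministic quota rounding: each class receives floor(n * p) units and the
#' remaining units go to the classes with the largest fractional remainders,
#' ties broken by class order as listed.
#'
#' @param p normalized class probabilities (named).
#' @param n total number of units (non-negative integer).
#' @return integer vector of class counts summing to `n`.
#' @export
largest_remainder <- function(p, n) {
  stopifnot(n >= 0)
  p <- normalize_marginal(p, warn_tol = Inf)
  quota <- p * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order(): ties keep the earlier-listed class first
    give <- order(-frac)[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(p)
  counts
}

# Evaluate a function under a temporary RNG state so callers' streams are
# untouched; every generator takes an explicit seed.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
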