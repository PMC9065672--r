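#' Jenks natural-breaks classification
#'
#' Computes the optimal partition of one-dimensional values into `k` contiguous
#' classes minimizing the total within-class sum of squared deviations (Fisher's
#' optimal classification, the criterion behind "natural breaks"). Used to bin
#' farm-to-village distances into close/medium/remote location classes.
#'
#' @param values numeric vector.
#' @param k number of classes (>= 1); must not exceed the number of distinct
#'   values.
#' @return numeric vector of `k - 1` break points. A value `v` belongs to class
#'   `j` when `breaks[j - 1] < v <= breaks[j]` (with implicit -Inf/Inf bounds);
#'   each break is the midpoint between the adjacent class boundary values.
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 10, 11, 50, 51), 3)
jenks_breaks <- function(values, k) {
  stopifnot(is.numeric(values), length(values) >= 1, k >= 1)
  x <- sort(values)
  ux <- unique(x)
  if (k > length(ux)) {
    stop(sprintf("infeasible classification: k = %d exceeds %d distinct values",
                 k, length(ux)))
  }
  if (k == 1) return(numeric(0))
  n <- length(x)

  # prefix sums for O(1) within-segment SSE
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_sse <- function(i, j) {
    # SSE of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    m <- j - i + 1
    s2 - s^2 / m
  }

  # dp[c, j]: minimal total SSE partitioning x[1..j] into c classes
  dp <- matrix(Inf, nrow = k, ncol = n)
  cut <- matrix(NA_integer_, nrow = k, ncol = n)
  for (j in seq_len(n)) dp[1, j] <- seg_sse(1, j)
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf
      arg <- NA_integer_
      for (i in c:j) {
        # last class is x[i..j]; a class must be non-empty
        v <- dp[c - 1, i - 1] + seg_sse(i, j)
        if (v < best - 1e-12) {
          best <- v
          arg <- i
        }
      }
      dp[c, j] <- best
      cut[c, j] <- arg
    }
  }

  # backtrack class start indices
  starts <- integer(k)
  j <- n
  for (c in k:2) {
    starts[c] <- cut[c, j]
    j <- starts[c] - 1
  }
  starts[1] <- 1
  upper <- c(starts[-1] - 1, n)
  # break between class c and c+1: midpoint of boundary values
  (x[upper[-k]] + x[starts[-1]]) / 2
}

#' Assign values to Jenks classes
#'
#' @param values numeric vector.
#' @param breaks break points from [jenks_breaks()].
#' @return integer class index in `1..(length(breaks) + 1)`, ordered by value.
#' @export
jenks_class <- function(values, breaks) {
  findInterval(values, breaks, left.open = TRUE) + 1L
}
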