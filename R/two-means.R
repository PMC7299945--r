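#' Exact two-cluster k-means in one dimension
#'
#' The optimal 1-d 2-means partition is a split of the sorted values, so
#' the global optimum is found by scanning all `n - 1` split points for
#' the one minimizing the total within-cluster sum of squares. This makes
#' every thresholding step of the hierarchical fND classification
#' deterministic: no random initialization, no Lloyd iterations.
#'
#' @param values Numeric vector, length >= 2, finite.
#' @return A list with
#'   \describe{
#'     \item{labels}{Integer vector (0 = low cluster, 1 = high cluster) in
#'       the original order; all 0 when degenerate.}
#'     \item{threshold}{Midpoint of the boundary pair of the optimal
#'       split (`NA` when degenerate).}
#'     \item{separation}{`|mean(high) - mean(low)|` (0 when degenerate).}
#'     \item{degenerate}{`TRUE` when all values are identical.}
#'   }
#' @examples
#' two_means_1d(c(0, 0, 0, 10, 10))$threshold  # 5
#' @export
two_means_1d <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) abort("`values` must have length >= 2.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  if (max(values) == min(values)) {
    return(list(
      labels = rep(0L, n), threshold = NA_real_,
      separation = 0, degenerate = TRUE
    ))
  }
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  tot <- cs[n]
  i <- seq_len(n - 1)
  # within-cluster SSE of split after position i; the sum-of-squares term
  # is constant across splits, so minimizing -(S1^2/i + S2^2/(n-i)) suffices
  crit <- -(cs[i]^2 / i + (tot - cs[i])^2 / (n - i))
  i_star <- which.min(crit) # first optimum on ties: deterministic
  lab_sorted <- c(rep(0L, i_star), rep(1L, n - i_star))
  labels <- integer(n)
  labels[ord] <- lab_sorted
  mean_lo <- cs[i_star] / i_star
  mean_hi <- (tot - cs[i_star]) / (n - i_star)
  list(
    labels = labels,
    threshold = (x[i_star] + x[i_star + 1]) / 2,
    separation = abs(mean_hi - mean_lo),
    degenerate = FALSE
  )
}
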