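#' Weighted block jackknife
#'
#' Combines per-block estimates of a genome-wide statistic into an overall
#' estimate and a weighted delete-one-block jackknife standard error
#' (Busing-Meijer-van der Leeden weighted jackknife), with block weights
#' typically the per-block SNP counts. Blocks with zero or missing weight
#' are dropped.
#'
#' @param block_estimates Numeric vector, the statistic computed within
#'   each block alone.
#' @param block_weights Non-negative weights (e.g. usable SNP counts).
#' @return A list with `estimate` (the weight-averaged whole-data value),
#'   `se`, `n_blocks`, and `bias_corrected` (the jackknife-debiased
#'   estimate).
#' @export
block_jackknife <- function(block_estimates, block_weights) {
  keep <- !is.na(block_estimates) & !is.na(block_weights) & block_weights > 0
  est <- block_estimates[keep]
  w <- block_weights[keep]
  g <- length(est)
  if (g < 2) abort("need at least two blocks with positive weight.")
  n <- sum(w)
  theta <- sum(w * est) / n
  loo <- (n * theta - w * est) / (n - w) # delete-one-block estimates
  h <- n / w
  theta_j <- g * theta - sum((1 - w / n) * loo)
  tau <- h * theta - (h - 1) * loo
  v <- mean((tau - theta_j)^2 / (h - 1))
  list(estimate = theta, se = sqrt(v), n_blocks = g, bias_corrected = theta_j)
}

# Jackknife from per-block sums and counts of per-SNP terms.
# S, counts: vectors over blocks; statistic is the mean over usable SNPs.
jackknife_from_sums <- function(S, counts) {
  keep <- counts > 0
  block_jackknife((S / counts)[keep], counts[keep])
}

# Weighted jackknife covariance for several statistics sharing the block
# structure. loo: g x K delete-one estimates; theta: length-K totals;
# w: g x K per-statistic block weights (or a vector recycled).
weighted_jackknife_cov <- function(loo, theta, w) {
  g <- nrow(loo)
  K <- ncol(loo)
  if (is.null(dim(w))) w <- matrix(w, g, K)
  n <- colSums(w)
  h <- sweep(1 / w, 2, n, "*") # h_jk = n_k / w_jk
  loo0 <- loo
  loo0[w == 0] <- 0 # blocks empty for a statistic contribute nothing
  theta_j <- g * theta - colSums((1 - sweep(w, 2, n, "/")) * loo0)
  tau <- h * matrix(theta, g, K, byrow = TRUE) - (h - 1) * loo
  dev <- sweep(tau, 2, theta_j, "-") / sqrt(h - 1)
  dev[w == 0] <- 0
  crossprod(dev) / g
}
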