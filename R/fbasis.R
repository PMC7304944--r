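# Basis machinery: per-block sums of corrected pairwise f2 terms over a
# fixed group set, from which every f2/f3/f4 (and its jackknife SE, and
# covariances) follows by linear combination. All statistics derived from
# one basis share the SNP set (sites where every group is observed), the
# convention for graph fitting.

fstat_basis <- function(freqs, groups, correction = TRUE) {
  check_groups(freqs, groups)
  k <- length(groups)
  m <- freqs$m[, groups, drop = FALSE]
  usable <- rowSums(m >= 1) == k
  if (sum(usable) == 0) abort("no SNPs observed in every group.")
  p <- freqs$p[usable, groups, drop = FALSE]
  block <- freqs$block[usable]
  corr <- if (correction) {
    bias_correction(p, m[usable, , drop = FALSE])
  } else {
    matrix(0, nrow(p), k)
  }

  pairs <- utils::combn(k, 2)
  K <- ncol(pairs)
  terms <- matrix(0, nrow(p), K)
  for (q in seq_len(K)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    terms[, q] <- (p[, i] - p[, j])^2 - corr[, i] - corr[, j]
  }
  blocks <- sort(unique(block))
  S <- rowsum(terms, block)
  counts <- rowsum(rep(1L, nrow(p)), block)[, 1]
  pair_names <- paste(groups[pairs[1, ]], groups[pairs[2, ]], sep = "|")
  colnames(S) <- pair_names

  structure(
    list(groups = groups, pairs = pairs, pair_names = pair_names,
         S = S, counts = counts, n_snps = nrow(p),
         n_blocks = length(counts), correction = correction),
    class = "pf_fbasis"
  )
}

pair_index <- function(basis, a, b) {
  ia <- match(a, basis$groups); ib <- match(b, basis$groups)
  q <- which((basis$pairs[1, ] == pmin(ia, ib)) &
               (basis$pairs[2, ] == pmax(ia, ib)))
  if (length(q) != 1) abort(sprintf("no basis pair for (%s, %s).", a, b))
  q
}

combo_f2 <- function(basis, A, B) {
  v <- numeric(length(basis$pair_names))
  v[pair_index(basis, A, B)] <- 1
  v
}

combo_f3 <- function(basis, C, A, B) {
  (combo_f2(basis, C, A) + combo_f2(basis, C, B) - combo_f2(basis, A, B)) / 2
}

combo_f4 <- function(basis, A, B, X, Y) {
  (combo_f2(basis, A, Y) + combo_f2(basis, B, X) -
     combo_f2(basis, A, X) - combo_f2(basis, B, Y)) / 2
}

# Estimates and jackknife SEs for a set of linear combinations (columns of
# C) of the basis pairs. Shared SNP set -> shared block weights.
combo_stats <- function(basis, C) {
  SC <- basis$S %*% C
  counts <- basis$counts
  g <- length(counts)
  n <- sum(counts)
  tot <- colSums(SC)
  theta <- tot / n
  loo <- sweep(-SC, 2, tot, "+") / (n - counts)
  h <- n / counts
  theta_j <- g * theta - colSums((1 - counts / n) * loo)
  tau <- outer(h, theta) - (h - 1) * loo
  v <- colMeans(sweep(tau, 2, theta_j, "-")^2 / (h - 1))
  list(estimate = theta, se = sqrt(v), n_blocks = g, n_snps = n)
}

# Full jackknife covariance for the combinations.
combo_cov <- function(basis, C) {
  SC <- basis$S %*% C
  counts <- basis$counts
  n <- sum(counts)
  tot <- colSums(SC)
  loo <- sweep(-SC, 2, tot, "+") / (n - counts)
  weighted_jackknife_cov(loo, tot / n, counts)
}
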