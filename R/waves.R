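# qpWave-style rank tests and qpAdm-style admixture weights on f4 matrices.

#' Matrix of f4 statistics between a left and a right population set
#'
#' Builds the `(|left| - 1) x (|right| - 1)` matrix
#' `X[i, j] = f4(left[i+1], left[1]; right[j+1], right[1])` together with
#' its block-resolved values and the weighted block-jackknife covariance of
#' `vec(X)`. The rank of this matrix counts the independent ancestry
#' streams relating the left populations to the right (outgroup) set.
#'
#' @param freqs A [group_freqs()] table.
#' @param left,right Disjoint label sets (first element of each is the
#'   within-set base).
#' @param allsnps If `FALSE` (intersection mode) every entry uses the SNPs
#'   observed in all left and right groups; if `TRUE` each entry uses the
#'   maximal SNP set where its own four groups are observed.
#' @return An object of class `pf_f4matrix`.
#' @export
build_f4_matrix <- function(freqs, left, right, allsnps = FALSE) {
  check_groups(freqs, left, distinct = TRUE)
  check_groups(freqs, right, distinct = TRUE)
  if (length(intersect(left, right))) {
    abort("left and right sets must be disjoint.")
  }
  if (length(left) < 2 || length(right) < 2) {
    abort("need at least two left and two right populations.")
  }
  nl1 <- length(left) - 1L
  nr1 <- length(right) - 1L
  K <- nl1 * nr1
  p <- freqs$p
  m <- freqs$m

  if (!allsnps) {
    usable <- rowSums(m[, c(left, right), drop = FALSE] >= 1) ==
      length(left) + length(right)
  }

  blocks <- sort(unique(freqs$block))
  g <- length(blocks)
  S <- matrix(0, g, K)
  W <- matrix(0, g, K)
  est <- numeric(K)
  k <- 0L
  for (j in seq_len(nr1)) {
    dr <- p[, right[j + 1]] - p[, right[1]]
    for (i in seq_len(nl1)) {
      k <- k + 1L
      terms <- (p[, left[i + 1]] - p[, left[1]]) * dr
      use <- if (allsnps) !is.na(terms) else usable & !is.na(terms)
      S[, k] <- rowsum(ifelse(use, terms, 0), freqs$block)[, 1]
      W[, k] <- rowsum(use * 1L, freqs$block)[, 1]
    }
  }
  nk <- colSums(W)
  if (any(nk == 0)) abort("an f4 entry has no usable SNPs.")
  est <- colSums(S) / nk
  loo <- sweep(-S, 2, colSums(S), "+") / sweep(-W, 2, nk, "+")
  cov <- weighted_jackknife_cov(loo, est, W)
  if (g < 2) abort("need at least two jackknife blocks.")

  X <- matrix(est, nl1, nr1,
              dimnames = list(left[-1], right[-1]))
  structure(
    list(X = X, est = est, cov = cov, left = left, right = right,
         block_sums = S, block_counts = W, n_snps = if (allsnps)
           max(nk) else sum(W[, 1]),
         n_blocks = g, allsnps = allsnps),
    class = "pf_f4matrix"
  )
}

#' @export
print.pf_f4matrix <- function(x, ...) {
  cat(sprintf("<pf_f4matrix> left base %s, right base %s; %d x %d entries\n",
              x$left[1], x$right[1], nrow(x$X), ncol(x$X)))
  print(signif(x$X, 4))
  invisible(x)
}

# Robust inverse of the jackknife covariance; ridge-regularized when the
# condition number exceeds 1e12 (lambda = 1e-6 * mean diagonal).
cov_inverse <- function(cov, warn_ridge = TRUE) {
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) / 1e12) {
    if (warn_ridge) warn("singular f4 covariance; ridge-regularized.")
    cov <- cov + diag(1e-6 * mean(diag(cov)), nrow(cov))
    ev <- eigen(cov, symmetric = TRUE)
  }
  ev$vectors %*% (t(ev$vectors) / ev$values)
}

# Alternating generalized least squares fit of a rank-k matrix to X under
# the covariance of vec(X). Returns fitted factors and the residual
# quadratic form.
rank_fit <- function(X, covinv, k, tol = 1e-10, max_iter = 1000,
                     init = NULL) {
  nl1 <- nrow(X); nr1 <- ncol(X)
  x <- as.vector(X)
  if (k == 0) {
    stat <- drop(t(x) %*% covinv %*% x)
    return(list(stat = stat, A = matrix(0, nl1, 0), B = matrix(0, nr1, 0),
                fitted = matrix(0, nl1, nr1), iter = 0L))
  }
  sv <- svd(X)
  A <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(k)]), k)
  B <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(k)]), k)
  if (!is.null(init)) { A <- init$A; B <- init$B }
  # permutation mapping vec(t(X)) entries into vec(X) positions
  perm <- as.vector(t(matrix(seq_len(nl1 * nr1), nl1, nr1)))
  covinv_t <- covinv[perm, perm]
  xt <- x[perm]
  obj <- Inf
  for (it in seq_len(max_iter)) {
    MB <- kronecker(B, diag(nl1))
    a <- solve(t(MB) %*% covinv %*% MB, t(MB) %*% covinv %*% x)
    A <- matrix(a, nl1, k)
    MA <- kronecker(A, diag(nr1))
    b <- solve(t(MA) %*% covinv_t %*% MA, t(MA) %*% covinv_t %*% xt)
    B <- matrix(b, nr1, k)
    r <- x - as.vector(A %*% t(B))
    new_obj <- drop(t(r) %*% covinv %*% r)
    if (is.finite(obj) && abs(obj - new_obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(stat = obj, A = A, B = B, fitted = A %*% t(B), iter = it)
}

#' qpWave-style rank test of an f4 matrix
#'
#' Tests whether the f4 matrix is consistent with rank `k` — i.e. with
#' `k + 1` independent streams of ancestry relating the left populations
#' to the right set. The best rank-`k` approximation is fitted by
#' alternating generalized least squares under the block-jackknife
#' covariance; the residual quadratic form is referred to a chi-square
#' distribution with `(|L| - 1 - k) (|R| - 1 - k)` degrees of freedom.
#'
#' @param f4m A [build_f4_matrix()] result.
#' @param k Tested rank, `0 <= k < min(|L| - 1, |R| - 1)`.
#' @return A one-row tibble: `rank`, `statistic`, `dof`, `p_value`,
#'   `n_snps`, `n_blocks`; the fitted factors are kept in attributes.
#' @export
rank_test <- function(f4m, k = 0) {
  stopifnot(inherits(f4m, "pf_f4matrix"))
  nl1 <- nrow(f4m$X); nr1 <- ncol(f4m$X)
  if (k < 0 || k >= min(nl1, nr1)) {
    abort(sprintf("rank k must satisfy 0 <= k < %d.", min(nl1, nr1)))
  }
  covinv <- cov_inverse(f4m$cov)
  fit <- rank_fit(f4m$X, covinv, k)
  dof <- (nl1 - k) * (nr1 - k)
  out <- tibble::tibble(
    rank = k, statistic = fit$stat, dof = dof,
    p_value = pchisq(fit$stat, dof, lower.tail = FALSE),
    n_snps = f4m$n_snps, n_blocks = f4m$n_blocks
  )
  attr(out, "fit") <- fit
  out
}

#' qpAdm-style admixture proportions
#'
#' Models a target population as a mixture of `N` source populations by
#' exploiting shared drift with a disjoint set of right (outgroup)
#' populations: the f4 matrix with left set `(target, sources)` must have
#' rank `N - 1`, and the mixing weights are the left null vector of the
#' fitted rank-deficient matrix, normalized to sum to 1 exactly. Standard
#' errors come from a delete-one-block jackknife of the entire solve, and
#' the model-fit p-value is the rank test of the residual.
#'
#' @param freqs A [group_freqs()] table.
#' @param target Target group label.
#' @param sources At least two source labels.
#' @param right Right/outgroup labels, disjoint from `target` and
#'   `sources`.
#' @param allsnps SNP-selection mode, as in [build_f4_matrix()].
#' @return An object of class `pf_qpadm`: `weights` tibble (source,
#'   weight, se, z), `p_value` for model fit, `rank_test` row, plus the
#'   underlying f4 matrix.
#' @export
qpadm_weights <- function(freqs, target, sources, right, allsnps = FALSE) {
  if (length(sources) < 2) abort("need at least two sources.")
  f4m <- build_f4_matrix(freqs, c(target, sources), right,
                         allsnps = allsnps)
  N <- length(sources)
  covinv <- cov_inverse(f4m$cov)

  solve_weights <- function(X) {
    fit <- rank_fit(X, covinv, N - 1)
    z <- svd(fit$A, nu = N, nv = 0)$u[, N]
    if (abs(sum(z)) < 1e-12) {
      abort("sources are collinear: the null vector has zero total weight.")
    }
    w <- z / sum(z)
    list(w = w, fit = fit)
  }
  full <- solve_weights(f4m$X)
  w_hat <- full$w
  if (any(!is.finite(w_hat))) abort("weight solve failed.")

  # delete-one-block jackknife of the whole solve
  g <- f4m$n_blocks
  tot_S <- colSums(f4m$block_sums)
  tot_W <- colSums(f4m$block_counts)
  loo_w <- matrix(NA_real_, g, N)
  for (j in seq_len(g)) {
    est_j <- (tot_S - f4m$block_sums[j, ]) / (tot_W - f4m$block_counts[j, ])
    Xj <- matrix(est_j, N, length(f4m$right) - 1)
    loo_w[j, ] <- tryCatch(solve_weights(Xj)$w, error = function(e) NA_real_)
  }
  bw <- rowMeans(f4m$block_counts)
  se <- vapply(seq_len(N), function(i) {
    ok <- !is.na(loo_w[, i])
    block_jackknife_loo_se(loo_w[ok, i], w_hat[i], bw[ok])
  }, numeric(1))

  rt <- rank_test(f4m, N - 1)
  structure(
    list(
      weights = tibble::tibble(
        source = sources, weight = w_hat, se = se,
        z = ifelse(se > 0, w_hat / se, NA_real_)),
      target = target, right = right,
      p_value = rt$p_value, rank_test = rt, f4_matrix = f4m,
      n_snps = f4m$n_snps, n_blocks = g
    ),
    class = "pf_qpadm"
  )
}

# Weighted jackknife SE from delete-one statistics of a non-linear solve
# (the statistic itself, not per-block means).
block_jackknife_loo_se <- function(loo, theta, w) {
  g <- length(loo)
  n <- sum(w)
  h <- n / w
  theta_j <- g * theta - sum((1 - w / n) * loo)
  tau <- h * theta - (h - 1) * loo
  sqrt(mean((tau - theta_j)^2 / (h - 1)))
}

#' @export
print.pf_qpadm <- function(x, ...) {
  cat(sprintf("<pf_qpadm> %s ~ %s (fit p = %.3g, %d SNPs)\n",
              x$target, paste(x$weights$source, collapse = " + "),
              x$p_value, x$n_snps))
  print(x$weights)
  invisible(x)
}

#' @export
tidy.pf_qpadm <- function(x, ...) x$weights

#' @export
glance.pf_qpadm <- function(x, ...) {
  tibble::tibble(target = x$target, p_value = x$p_value,
                 statistic = x$rank_test$statistic, dof = x$rank_test$dof,
                 n_snps = x$n_snps, n_blocks = x$n_blocks)
}

#' Homogeneity scan over candidate analysis clusters
#'
#' The grouping protocol for deciding whether ancient individuals can be
#' co-analysed as one population: for every pair of members within a
#' candidate group, (1) symmetry statistics
#' `f4(base, test; member1, member2)` are computed over a panel of test
#' populations and the pair is flagged if any |Z| exceeds `z_threshold`,
#' and (2) a rank-0 qpWave test of the pair against the outgroup set asks
#' whether the two members are consistent with a single stream of
#' ancestry. A group passes only if no pair is flagged by either check;
#' failing groups are reported with the offending pairs for manual
#' splitting.
#'
#' @param dataset A `pf_dataset`.
#' @param candidate_groups Named list mapping a group label to the member
#'   sample ids; default: every dataset group with at least two samples.
#' @param test_pops Group labels iterated as `test` in the f4 scan.
#' @param outgroups Group labels for the rank test (first is also the f4
#'   base).
#' @param z_threshold Flagging threshold on |Z| (default 3).
#' @param alpha Significance level for the rank-0 rejection.
#' @param inbreed Frequency counting mode, see [group_freqs()].
#' @return An object of class `pf_homogeneity`: `pairs` tibble (per-pair
#'   diagnostics) and `groups` tibble (per-group pass/fail).
#' @export
homogeneity_scan <- function(dataset, candidate_groups = NULL, test_pops,
                             outgroups, z_threshold = 3, alpha = 0.05,
                             inbreed = TRUE) {
  stopifnot(inherits(dataset, "pf_dataset"))
  if (is.null(candidate_groups)) {
    tab <- table(dataset$ind$group)
    cand <- names(tab)[tab >= 2]
    cand <- setdiff(cand, c(test_pops, outgroups))
    candidate_groups <- lapply(setNames(cand, cand), function(gr) {
      dataset$ind$sample_id[dataset$ind$group == gr]
    })
  }
  members <- unlist(candidate_groups, use.names = FALSE)
  grouping <- tibble::tibble(
    sample_id = dataset$ind$sample_id,
    group = ifelse(dataset$ind$sample_id %in% members,
                   dataset$ind$sample_id, dataset$ind$group)
  )
  freqs <- group_freqs(dataset, grouping, inbreed = inbreed)
  base <- outgroups[1]

  pair_rows <- list()
  for (gname in names(candidate_groups)) {
    ids <- candidate_groups[[gname]]
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    for (q in seq_len(ncol(prs))) {
      m1 <- prs[1, q]; m2 <- prs[2, q]
      zs <- vapply(test_pops, function(tp) {
        f4_stat(freqs, base, tp, m1, m2)$z
      }, numeric(1))
      worst <- which.max(abs(zs))
      rank_p <- tryCatch(
        rank_test(build_f4_matrix(freqs, c(m1, m2), outgroups,
                                  allsnps = TRUE), 0)$p_value,
        error = function(e) NA_real_)
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        group = gname, member_1 = m1, member_2 = m2,
        max_abs_z = abs(zs[worst]), worst_test = test_pops[worst],
        rank0_p = rank_p,
        f4_flagged = abs(zs[worst]) > z_threshold,
        rank_rejected = !is.na(rank_p) & rank_p < alpha
      )
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  pairs$pass <- !pairs$f4_flagged & !pairs$rank_rejected
  groups <- pairs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_pairs = dplyr::n(), pass = all(.data$pass),
                     .groups = "drop")
  structure(list(pairs = pairs, groups = groups,
                 z_threshold = z_threshold, alpha = alpha),
            class = "pf_homogeneity")
}

#' @export
print.pf_homogeneity <- function(x, ...) {
  cat(sprintf("<pf_homogeneity> %d groups scanned (|Z| > %g, alpha = %g)\n",
              nrow(x$groups), x$z_threshold, x$alpha))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.pf_homogeneity <- function(x, ...) x$pairs
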