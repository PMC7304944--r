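# Structure summaries: distance transforms, MDS, NJ trees, projection PCA.

#' Convert an outgroup-f3 matrix to distances
#'
#' More shared drift means genetically closer, so outgroup-f3 similarities
#' become distances either by subtracting the values from 1 (`one_minus`,
#' used for MDS) or by taking their inverse (`inverse`, used for
#' neighbour-joining trees). The diagonal is forced to zero; both
#' transforms are monotone-decreasing in f3 and preserve symmetry.
#'
#' @param f3_matrix A [outgroup_f3_matrix()] result or a plain symmetric
#'   matrix of f3 values.
#' @param transform `"one_minus"` or `"inverse"`.
#' @return A symmetric distance matrix with attribute `transform`.
#' @export
to_distances <- function(f3_matrix, transform = c("one_minus", "inverse")) {
  transform <- match.arg(transform)
  est <- if (inherits(f3_matrix, "pf_f3matrix")) f3_matrix$estimate
         else as.matrix(f3_matrix)
  if (any(is.na(est[upper.tri(est)]))) {
    abort("f3 matrix has missing off-diagonal entries.")
  }
  if (transform == "inverse" && any(est[upper.tri(est)] <= 0)) {
    bad <- which(est <= 0 & upper.tri(est), arr.ind = TRUE)[1, ]
    abort(sprintf("inverse transform requires f3 > 0; violated for (%s, %s).",
                  rownames(est)[bad[1]], colnames(est)[bad[2]]))
  }
  d <- switch(transform, one_minus = 1 - est, inverse = 1 / est)
  diag(d) <- 0
  attr(d, "transform") <- transform
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared-distance matrix and embeds on the top
#' eigenpairs; distances between points that are exactly
#' Euclidean-realizable in `n_dims` dimensions are reproduced exactly.
#'
#' @param distances Symmetric distance matrix (e.g. [to_distances()]).
#' @param n_dims Number of output dimensions.
#' @return A tibble of class `pf_embedding` with columns `label` and
#'   `dim1..dimk`; attributes `eigenvalues` and `var_explained` (fractions
#'   of total positive-eigenvalue variation).
#' @export
mds_embed <- function(distances, n_dims = 2) {
  d <- as.matrix(distances)
  n <- nrow(d)
  stopifnot(n >= 2, n_dims >= 1)
  k <- min(n_dims, n - 1)
  fit <- cmdscale(d, k = k, eig = TRUE)
  pos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (n_dims > pos) {
    warn(sprintf(
      "requested %d dimensions but only %d positive eigenvalues; truncated.",
      n_dims, pos))
    k <- max(pos, 1)
  }
  pts <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  if (ncol(pts) < k) { # degenerate input: pad with zero coordinates
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  labels <- rownames(d) %||% paste0("obs", seq_len(n))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(pts), paste0("dim", seq_len(ncol(pts)))))
  out <- dplyr::bind_cols(tibble::tibble(label = labels), out)
  eigv <- fit$eig
  attr(out, "eigenvalues") <- eigv
  attr(out, "var_explained") <- pmax(eigv, 0) / sum(pmax(eigv, 0))
  class(out) <- c("pf_embedding", class(out))
  out
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}), rooted on the edge
#' leading to `outgroup`. Negative branch lengths, which NJ can produce on
#' non-additive distances, are clamped to zero and the total deficit is
#' reported as a message.
#'
#' @param distances Symmetric distance matrix with row/column names.
#' @param outgroup Label to root on.
#' @return A rooted `phylo` object (serialize with [ape::write.tree()]).
#' @export
nj_tree <- function(distances, outgroup) {
  d <- as.matrix(distances)
  if (nrow(d) < 3) abort("need at least three labels.")
  if (!outgroup %in% rownames(d)) {
    abort(sprintf("outgroup '%s' not among labels.", outgroup))
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    inform(sprintf("clamped %d negative NJ branch length(s); deficit %.4g.",
                   sum(neg), -sum(tree$edge.length[neg])))
    tree$edge.length[neg] <- 0
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Projection principal component analysis
#'
#' Components are fitted on a diploid modern panel only: SNPs are centered
#' by the modern mean dosage and scaled by `sqrt(p (1 - p))` of the modern
#' allele frequency (missing panel entries are mean-imputed for the fit
#' stage). Each ancient sample is then projected by least squares of its
#' standardized calls against the SNP loadings restricted to its
#' non-missing sites, so low-coverage pseudo-haploid samples obtain
#' coordinates on the modern axes without distorting them. Eigenvector
#' signs are fixed by making the largest-magnitude loading positive.
#'
#' @param dataset A `pf_dataset`.
#' @param modern Sample ids (or group labels) forming the fit panel.
#' @param ancients Sample ids (or group labels) to project; default all
#'   remaining samples.
#' @param n_components Number of components.
#' @return A tibble of class `pf_embedding` with columns `sample`, `group`,
#'   `role` (`"modern"`/`"projected"`) and `dim1..dimk`; attributes
#'   `eigenvalues`, `var_explained` and `n_snps`. Ancients with zero
#'   overlapping called SNPs get `NA` coordinates and a warning.
#' @export
pca_fit_project <- function(dataset, modern, ancients = NULL,
                            n_components = 2) {
  stopifnot(inherits(dataset, "pf_dataset"))
  expand <- function(x) {
    hit <- x %in% dataset$ind$sample_id
    c(x[hit], dataset$ind$sample_id[dataset$ind$group %in% x[!hit]])
  }
  modern <- expand(modern)
  ancients <- if (is.null(ancients)) {
    setdiff(dataset$ind$sample_id, modern)
  } else {
    expand(ancients)
  }
  mi <- match(modern, dataset$ind$sample_id)
  Gm <- dataset$geno[, mi, drop = FALSE]
  pbar <- rowMeans(Gm, na.rm = TRUE) / 2
  keep <- !is.na(pbar) & pbar > 0 & pbar < 1
  if (!any(keep)) abort("no polymorphic SNPs in the modern panel.")
  Gm <- Gm[keep, , drop = FALSE]
  pbar <- pbar[keep]
  scale <- sqrt(pbar * (1 - pbar))
  X <- (Gm - 2 * pbar) / scale
  X[is.na(X)] <- 0 # mean imputation, fit stage only
  k <- min(n_components, length(modern) - 1)
  sv <- svd(t(X))
  V <- sv$v[, seq_len(k), drop = FALSE]
  U <- sv$u[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(c) {
    sign(V[which.max(abs(V[, c])), c])
  }, numeric(1))
  V <- sweep(V, 2, flip, "*")
  U <- sweep(U, 2, flip, "*")
  scores_m <- U %*% diag(sv$d[seq_len(k)], k)

  proj <- matrix(NA_real_, length(ancients), k)
  for (i in seq_along(ancients)) {
    ai <- match(ancients[i], dataset$ind$sample_id)
    y <- (dataset$geno[keep, ai] - 2 * pbar) / scale
    obs <- !is.na(y)
    if (!any(obs)) {
      warn(sprintf("sample '%s' has no overlap with the panel SNPs; left unprojected.",
                   ancients[i]))
      next
    }
    Vo <- V[obs, , drop = FALSE]
    proj[i, ] <- solve(crossprod(Vo), crossprod(Vo, y[obs]))
  }

  coords <- rbind(scores_m, proj)
  all_ids <- c(modern, ancients)
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(coords), paste0("dim", seq_len(k))))
  out <- dplyr::bind_cols(
    tibble::tibble(
      sample = all_ids,
      group = dataset$ind$group[match(all_ids, dataset$ind$sample_id)],
      role = rep(c("modern", "projected"),
                 c(length(modern), length(ancients)))),
    out)
  ev <- sv$d^2
  attr(out, "eigenvalues") <- ev
  attr(out, "var_explained") <- ev[seq_len(k)] / sum(ev)
  attr(out, "n_snps") <- sum(keep)
  class(out) <- c("pf_embedding", class(out))
  out
}
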