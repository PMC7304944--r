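# Admixture dating from the decay of weighted allele covariance with
# genetic distance.

#' Weighted allele-covariance decay curve
#'
#' For an admixed target and two reference (source) populations, each SNP
#' gets a weight `w = pA - pB` (the allele-frequency contrast of the
#' sources) and each target sample a per-SNP residual
#' `r = t - (theta pA + (1 - theta) pB)`, where `t` is the sample's call
#' on the frequency scale and `theta` the pooled least-squares ancestry
#' proportion. Admixture generates covariance between the weighted
#' residuals of linked SNPs that decays as `exp(-g d)` with genetic
#' distance `d` (Morgans) at a rate equal to the number of generations
#' `g` since the admixture pulse. The curve accumulates the product
#' `(w r)_s1 (w r)_s2`, averaged over samples and intra-chromosome SNP
#' pairs binned by `|d1 - d2|`, and is kept per chromosome for a
#' delete-one-chromosome jackknife. Accumulating per sample (rather than
#' on the sample-averaged frequency) preserves each sample's tract
#' structure as an independent realization, which is what makes the decay
#' rate estimable from modest panels.
#'
#' @param target Matrix of target calls (SNPs x samples/haplotypes) on any
#'   dosage scale (`NA` allowed), or a vector of target allele
#'   frequencies (treated as a single sample).
#' @param freq_a,freq_b Reference allele-frequency vectors over the SNPs.
#' @param map Data frame with columns `chromosome` and `genetic_pos`
#'   (Morgans).
#' @param bin_width Bin width in Morgans (default 0.001 = 0.1 cM).
#' @param max_dist Largest pair distance retained (Morgans).
#' @param ploidy Dosage scale of `target` rows (1 for haplotypes, 2 for
#'   diploid dosages); ignored when `target` is already a frequency
#'   vector.
#' @return An object of class `pf_decay`: `curve` tibble (`bin_mid`,
#'   `cov`, `n_pairs`), per-chromosome sums for the jackknife, and the
#'   fitted ancestry proportion `theta`.
#' @export
weighted_cov_curve <- function(target, freq_a, freq_b, map,
                               bin_width = 0.001, max_dist = 0.5,
                               ploidy = 1) {
  map <- tibble::as_tibble(map)
  n_snps <- nrow(map)
  if (!is.matrix(target)) target <- matrix(target, ncol = 1)
  stopifnot(nrow(target) == n_snps, length(freq_a) == n_snps,
            length(freq_b) == n_snps)
  tf <- target / ploidy # frequency scale, SNPs x samples
  ok <- stats::complete.cases(freq_a, freq_b)
  w <- freq_a - freq_b
  tbar <- rowMeans(tf, na.rm = TRUE)
  denom <- sum(w[ok]^2, na.rm = TRUE)
  theta <- if (denom > 0) {
    sum(((tbar - freq_b) * w)[ok], na.rm = TRUE) / denom
  } else {
    0.5 # refA = refB carries no ancestry information
  }
  fitted_mean <- theta * freq_a + (1 - theta) * freq_b
  X <- w * (tf - fitted_mean) # SNPs x samples weighted residuals
  obs <- !is.na(X) & ok
  X[!obs] <- 0

  nbins <- ceiling(max_dist / bin_width)
  chroms <- unique(map$chromosome)
  sums <- matrix(0, length(chroms), nbins,
                 dimnames = list(as.character(chroms), NULL))
  cnts <- matrix(0, length(chroms), nbins,
                 dimnames = list(as.character(chroms), NULL))
  for (ci in seq_along(chroms)) {
    idx <- which(map$chromosome == chroms[ci])
    if (length(idx) < 2) next
    d <- map$genetic_pos[idx]
    # sample-summed pair products and pair counts in one BLAS call each
    P <- tcrossprod(X[idx, , drop = FALSE])
    N <- tcrossprod(obs[idx, , drop = FALSE] * 1)
    bin <- ceiling(abs(outer(d, d, "-")) / bin_width)
    ut <- upper.tri(bin)
    bin <- bin[ut]
    keep <- bin >= 1 & bin <= nbins
    if (!any(keep)) next
    bs <- rowsum(cbind(P[ut][keep], N[ut][keep]), bin[keep])
    sums[ci, as.integer(rownames(bs))] <- bs[, 1]
    cnts[ci, as.integer(rownames(bs))] <- bs[, 2]
  }
  tot_n <- colSums(cnts)
  if (sum(tot_n) == 0) abort("no SNP pairs in the distance range.")
  curve <- tibble::tibble(
    bin_mid = (seq_len(nbins) - 0.5) * bin_width,
    cov = ifelse(tot_n > 0, colSums(sums) / tot_n, NA_real_),
    n_pairs = tot_n
  )
  structure(list(curve = curve, chrom_sums = sums, chrom_counts = cnts,
                 bin_width = bin_width, theta = theta),
            class = "pf_decay")
}

#' @export
print.pf_decay <- function(x, ...) {
  cat(sprintf(
    "<pf_decay> %d bins of %.3g cM; fitted ancestry proportion %.3f\n",
    nrow(x$curve), 100 * x$bin_width, x$theta))
  invisible(x)
}

#' @export
tidy.pf_decay <- function(x, ...) x$curve

#' Fit an exponential decay and convert to an admixture date
#'
#' Least-squares fit of `a exp(-g d) + c` to the binned covariance curve
#' over `[d_min, d_max]` (distances in Morgans, so the decay rate `g` is
#' in generations). The affine term `c` absorbs assortative or background
#' covariance. The standard error of `g` comes from delete-one-chromosome
#' refits combined with the weighted jackknife; the date in years is
#' `g * generation_time`.
#'
#' The default fit range starts at 0.45 cM: at shorter distances real data
#' carry background LD that is not admixture-generated and would bias the
#' decay, so the convention is to exclude them.
#'
#' @param decay A [weighted_cov_curve()] result.
#' @param d_min,d_max Fit range in Morgans (defaults 0.0045 and 0.5, i.e.
#'   0.45-50 cM).
#' @param generation_time Years per generation (default 28.5).
#' @return A one-row tibble of class `pf_date`: `g` (generations), `se_g`,
#'   `amplitude`, `offset`, `date_years = g * generation_time`,
#'   `se_years`, `n_bins`, `signal` (`FALSE` when the fitted rate is not
#'   positive, in which case no date should be quoted).
#' @export
fit_decay <- function(decay, d_min = 0.0045, d_max = 0.5,
                      generation_time = 28.5) {
  stopifnot(inherits(decay, "pf_decay"))
  fit_one <- function(curve) {
    use <- curve$n_pairs > 0 & curve$bin_mid >= d_min &
      curve$bin_mid <= d_max & !is.na(curve$cov)
    if (sum(use) < 5) abort("fewer than 5 usable bins in the fit range.")
    d <- curve$bin_mid[use]
    y <- curve$cov[use]
    wts <- curve$n_pairs[use]
    # profile objective: for fixed g, (amplitude, offset) solve by
    # weighted linear least squares, making the 1-D search in g robust
    profile <- function(g) {
      e <- exp(-g * d)
      fit <- lm(y ~ e, weights = wts)
      list(rss = sum(wts * fit$residuals^2),
           a = unname(coef(fit)[2]), c = unname(coef(fit)[1]))
    }
    grid <- exp(seq(log(0.5 / max(d)), log(5 / min(d)), length.out = 60))
    rss <- vapply(grid, function(g) profile(g)$rss, numeric(1))
    gbest <- grid[which.min(rss)]
    opt <- stats::optimize(function(g) profile(g)$rss,
                           lower = gbest / 3, upper = gbest * 3,
                           tol = 1e-10)
    pr <- profile(opt$minimum)
    par <- c(pr$a, opt$minimum, pr$c)
    obj <- function(p) sum(wts * (y - (p[1] * exp(-p[2] * d) + p[3]))^2)
    fit <- optim(par, obj, method = "L-BFGS-B",
                 lower = c(-Inf, 1e-8, -Inf),
                 control = list(maxit = 5000, factr = 1))
    fit$par
  }
  par <- fit_one(decay$curve)

  n_chrom <- nrow(decay$chrom_sums)
  loo_g <- rep(NA_real_, n_chrom)
  wts_c <- rowSums(decay$chrom_counts)
  if (n_chrom >= 2) {
    for (ci in seq_len(n_chrom)) {
      s <- colSums(decay$chrom_sums[-ci, , drop = FALSE])
      n <- colSums(decay$chrom_counts[-ci, , drop = FALSE])
      cv <- tibble::tibble(bin_mid = decay$curve$bin_mid,
                           cov = ifelse(n > 0, s / n, NA_real_),
                           n_pairs = n)
      loo_g[ci] <- tryCatch(fit_one(cv)[2], error = function(e) NA_real_)
    }
  }
  ok <- !is.na(loo_g) & wts_c > 0
  se_g <- if (sum(ok) >= 2) {
    block_jackknife_loo_se(loo_g[ok], par[2], wts_c[ok])
  } else {
    NA_real_
  }
  signal <- par[2] > 0 && par[1] > 0
  out <- tibble::tibble(
    g = par[2], se_g = se_g, amplitude = par[1], offset = par[3],
    generation_time = generation_time,
    date_years = par[2] * generation_time,
    se_years = se_g * generation_time,
    n_bins = sum(decay$curve$n_pairs > 0 &
                   decay$curve$bin_mid >= d_min &
                   decay$curve$bin_mid <= d_max),
    signal = signal
  )
  if (!signal) {
    warn("fitted decay rate is not positive: no admixture-date signal.")
  }
  class(out) <- c("pf_date", class(out))
  out
}

#' @export
glance.pf_date <- function(x, ...) x
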