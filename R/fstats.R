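# f2 / f3 / f4 statistics with weighted block-jackknife standard errors.

fstat_result <- function(kind, pops, terms, block, n_min_blocks = 2) {
  usable <- !is.na(terms)
  if (sum(usable) == 0) abort("no usable SNPs for this statistic.")
  S <- rowsum(ifelse(usable, terms, 0), block)
  counts <- rowsum(usable * 1L, block)[, 1]
  ok <- counts > 0
  if (sum(ok) < n_min_blocks) {
    warn(sprintf("only %d non-empty jackknife block(s); SE unavailable.",
                 sum(ok)))
    jk <- list(estimate = sum(S[, 1]) / sum(counts), se = NA_real_,
               n_blocks = sum(ok))
  } else {
    jk <- jackknife_from_sums(S[, 1], counts)
  }
  pops <- c(pops, rep(NA_character_, 4 - length(pops)))
  tibble::tibble(
    kind = kind,
    pop1 = pops[1], pop2 = pops[2], pop3 = pops[3], pop4 = pops[4],
    estimate = jk$estimate, se = jk$se,
    z = ifelse(jk$se > 0, jk$estimate / jk$se, NA_real_),
    n_snps = sum(usable), n_blocks = jk$n_blocks
  )
}

#' f4 statistic
#'
#' `f4(A, B; X, Y)`: the mean over usable SNPs of
#' `(pA - pB) * (pX - pY)`. A value consistent with zero means `(A, B)`
#' form a clade with respect to `(X, Y)`; the sign indicates which pairs
#' share excess drift. Standard errors come from the weighted block
#' jackknife over the dataset's 5-Mb blocks. A SNP is usable when all four
#' groups have at least one observed allele; for a single statistic this
#' maximal per-statistic set coincides with the four-way intersection, so
#' `allsnps` only changes bookkeeping for matrix-valued computations (see
#' [build_f4_matrix()]).
#'
#' @param freqs A [group_freqs()] table.
#' @param A,B,X,Y Group labels (distinct).
#' @param allsnps Recorded SNP-selection mode.
#' @return A one-row tibble: `kind`, populations, `estimate`, `se`, `z`,
#'   `n_snps`, `n_blocks`.
#' @export
f4_stat <- function(freqs, A, B, X, Y, allsnps = FALSE) {
  check_groups(freqs, c(A, B, X, Y))
  check_groups(freqs, c(A, B), distinct = TRUE)
  check_groups(freqs, c(X, Y), distinct = TRUE)
  p <- freqs$p
  terms <- (p[, A] - p[, B]) * (p[, X] - p[, Y])
  out <- fstat_result("f4", c(A, B, X, Y), terms, freqs$block)
  out$allsnps <- allsnps
  out
}

#' f3 statistic
#'
#' `f3(C; A, B)`: the mean of `(pC - pA) * (pC - pB)` minus the
#' sampling-bias correction `h_C / m_C` for the target's finite allele
#' count, where `h_C = pC (1 - pC) m_C / (m_C - 1)`. Significantly
#' negative values are direct evidence that `C` is admixed between
#' populations related to `A` and `B`. With frequencies built in inbreed
#' mode, `m_C` counts one allele copy per pseudo-haploid individual; sites
#' where `m_C = 1` carry no heterozygosity information and their
#' correction is skipped.
#'
#' @param freqs A [group_freqs()] table.
#' @param C Target group; `A`, `B` the reference pair.
#' @param A,B Reference group labels.
#' @param correction Apply the target bias correction (disable to obtain
#'   the plain frequency-moment value).
#' @return A one-row tibble as in [f4_stat()].
#' @export
f3_stat <- function(freqs, C, A, B, correction = TRUE) {
  check_groups(freqs, c(C, A, B))
  check_groups(freqs, c(A, B), distinct = TRUE)
  p <- freqs$p
  terms <- (p[, C] - p[, A]) * (p[, C] - p[, B])
  if (correction) {
    terms <- terms - bias_correction(p[, C], freqs$m[, C])
  }
  out <- fstat_result("f3", c(C, A, B), terms, freqs$block)
  out$correction <- correction
  out
}

#' f2 statistic
#'
#' `f2(A, B)`: the mean of `(pA - pB)^2` minus the sampling-bias
#' corrections for both groups; the squared-drift distance between two
#' populations and the basis statistic from which f3 and f4 derive via
#' `f3(C; A, B) = (f2(C,A) + f2(C,B) - f2(A,B)) / 2` and
#' `f4(A, B; X, Y) = (f2(A,Y) + f2(B,X) - f2(A,X) - f2(B,Y)) / 2`.
#'
#' @inheritParams f3_stat
#' @param A,B Group labels.
#' @return A one-row tibble as in [f4_stat()].
#' @export
f2_stat <- function(freqs, A, B, correction = TRUE) {
  check_groups(freqs, c(A, B), distinct = TRUE)
  p <- freqs$p
  terms <- (p[, A] - p[, B])^2
  if (correction) {
    terms <- terms - bias_correction(p[, A], freqs$m[, A]) -
      bias_correction(p[, B], freqs$m[, B])
  }
  out <- fstat_result("f2", c(A, B), terms, freqs$block)
  out$correction <- correction
  out
}

#' Outgroup-f3 matrix
#'
#' `f3(outgroup; i, j)` for every pair of groups: the shared drift of `i`
#' and `j` since their common ancestor with a distant outgroup. Larger
#' values mean more shared ancestry; the matrix is the substrate for MDS
#' ([to_distances()] with `1 - f3`) and neighbour-joining trees (`1 / f3`).
#'
#' @param freqs A [group_freqs()] table.
#' @param outgroup Outgroup label (the f3 target).
#' @param groups Groups to compare; default all except the outgroup.
#' @param correction Bias-correct the outgroup as in [f3_stat()].
#' @return An object of class `pf_f3matrix`: symmetric matrices `estimate`,
#'   `se`, `z`, `n_snps` (diagonal `NA`) plus a long-format tibble.
#' @export
outgroup_f3_matrix <- function(freqs, outgroup, groups = NULL,
                               correction = TRUE) {
  if (is.null(groups)) groups <- setdiff(freqs$groups, outgroup)
  check_groups(freqs, c(outgroup, groups), distinct = TRUE)
  if (length(groups) < 2) abort("need at least two groups.")
  k <- length(groups)
  est <- se <- z <- nsnp <- matrix(NA_real_, k, k,
                                   dimnames = list(groups, groups))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- f3_stat(freqs, outgroup, groups[i], groups[j],
                   correction = correction)
      est[i, j] <- est[j, i] <- r$estimate
      se[i, j] <- se[j, i] <- r$se
      z[i, j] <- z[j, i] <- r$z
      nsnp[i, j] <- nsnp[j, i] <- r$n_snps
      rows[[length(rows) + 1]] <- r
    }
  }
  structure(
    list(estimate = est, se = se, z = z, n_snps = nsnp,
         outgroup = outgroup, groups = groups,
         table = dplyr::bind_rows(rows)),
    class = "pf_f3matrix"
  )
}

#' @export
print.pf_f3matrix <- function(x, ...) {
  cat(sprintf("<pf_f3matrix> outgroup-f3(%s; i, j) over %d groups\n",
              x$outgroup, length(x$groups)))
  print(round(x$estimate, 4))
  invisible(x)
}

#' @export
tidy.pf_f3matrix <- function(x, ...) x$table
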