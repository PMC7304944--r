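#' Pooled allele frequencies per group
#'
#' Pools alternative-allele counts within groups. In the default (diploid)
#' counting mode every sample contributes two allele copies per called
#' site. In `inbreed` mode — the convention for pseudo-haploid ancient
#' data, where the stored homozygous call really is a single sampled
#' allele — pseudo-haploid samples contribute one allele copy (dosage 0 or
#' 1) per called site, so that downstream sampling-bias corrections see the
#' true number of independent allele draws.
#'
#' @param dataset A `pf_dataset`.
#' @param grouping `NULL` to use the dataset's group labels, or a data
#'   frame with columns `sample_id`, `group` (samples omitted from the
#'   table are excluded).
#' @param inbreed Logical; count pseudo-haploid samples as single allele
#'   copies.
#' @return An object of class `pf_freqs`: matrices `count`, `m` (observed
#'   allele copies) and `p = count / m` (SNPs x groups, `NA` where a group
#'   has no data), plus the SNP table and block assignment.
#' @export
group_freqs <- function(dataset, grouping = NULL, inbreed = FALSE) {
  stopifnot(inherits(dataset, "pf_dataset"))
  if (is.null(grouping)) {
    grouping <- tibble::tibble(sample_id = dataset$ind$sample_id,
                               group = dataset$ind$group)
  }
  grouping <- tibble::as_tibble(grouping)
  idx <- match(grouping$sample_id, dataset$ind$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown sample id '%s' in grouping.",
                  grouping$sample_id[which(is.na(idx))[1]]))
  }
  g <- dataset$geno[, idx, drop = FALSE]
  ploidy <- dataset$ind$ploidy[idx]
  groups <- unique(grouping$group)
  Z <- outer(grouping$group, groups, "==") * 1

  scale <- ifelse(inbreed & ploidy == "pseudo_haploid", 0.5, 1)
  copies <- ifelse(inbreed & ploidy == "pseudo_haploid", 1, 2)

  called <- !is.na(g)
  g0 <- g
  g0[!called] <- 0L
  count <- (g0 %*% (Z * scale))
  m <- (called %*% (Z * copies))
  p <- count / m
  p[m == 0] <- NA_real_
  dimnames(count) <- dimnames(m) <- dimnames(p) <-
    list(dataset$snp$snp_id, groups)

  structure(
    list(count = count, m = m, p = p,
         block = dataset$snp$block_id, snp = dataset$snp,
         groups = groups, inbreed = inbreed),
    class = "pf_freqs"
  )
}

#' @export
print.pf_freqs <- function(x, ...) {
  cat(sprintf("<pf_freqs> %d SNPs x %d groups (inbreed mode: %s)\n",
              nrow(x$p), length(x$groups), x$inbreed))
  invisible(x)
}

check_groups <- function(freqs, groups, distinct = FALSE) {
  missing <- setdiff(groups, freqs$groups)
  if (length(missing)) {
    abort(sprintf("unknown group label(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (distinct && anyDuplicated(groups)) {
    abort("group labels must be distinct.")
  }
  invisible(groups)
}

# Per-site sampling-bias correction h_hat / m = p (1 - p) / (m - 1).
# Skipped (0) where m < 2, where the single allele draw carries no
# within-group heterozygosity information.
bias_correction <- function(p, m) {
  corr <- p * (1 - p) / (m - 1)
  corr[!is.finite(corr)] <- 0
  corr[m < 2] <- 0
  corr
}
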