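#' Construct a genotype dataset
#'
#' The central container of the package: an allele-dosage matrix (SNPs in
#' rows, samples in columns) together with per-SNP and per-sample metadata.
#' Dosages are counts of the alternative allele, coded `0`, `1`, `2` with
#' `NA` for missing. Pseudo-haploid samples — ancient individuals genotyped
#' by drawing a single random sequence per site — carry only `{0, 2, NA}`:
#' the random allele is stored as a homozygous call so that diploid and
#' haploid samples share one matrix code path.
#'
#' SNPs are assigned to contiguous genomic blocks (default 5 Mb windows per
#' chromosome) at construction time; all jackknife resampling downstream
#' uses these blocks.
#'
#' @param geno Integer matrix, SNPs x samples, values in `{0, 1, 2, NA}`.
#' @param snp Data frame with columns `snp_id`, `chromosome`, `genetic_pos`
#'   (Morgans), `physical_pos` (1-based bp), `ref_allele`, `alt_allele`, and
#'   optionally `is_cpg_transition` (logical, default `FALSE`).
#' @param ind Data frame with columns `sample_id`, `group`, and optionally
#'   `sex` (`"M"`, `"F"`, `"U"`), `ploidy` (`"diploid"` or
#'   `"pseudo_haploid"`; default inferred: samples carrying any heterozygous
#'   call are diploid) and `udg` (`"half"`, `"plus"`, `"minus"`).
#' @param block_size Block length in base pairs for jackknife windows.
#' @param provenance Free-text note carried along with the dataset.
#'
#' @return An object of class `pf_dataset`.
#' @export
genotype_dataset <- function(geno, snp, ind, block_size = 5e6,
                             provenance = "") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- tibble::as_tibble(snp)
  ind <- tibble::as_tibble(ind)

  req_snp <- c("snp_id", "chromosome", "genetic_pos", "physical_pos",
               "ref_allele", "alt_allele")
  if (!all(req_snp %in% names(snp))) {
    abort(paste0("`snp` must have columns: ", paste(req_snp, collapse = ", ")))
  }
  if (!all(c("sample_id", "group") %in% names(ind))) {
    abort("`ind` must have columns `sample_id` and `group`.")
  }
  if (nrow(geno) != nrow(snp)) {
    abort(sprintf("geno has %d rows but snp table has %d records.",
                  nrow(geno), nrow(snp)))
  }
  if (ncol(geno) != nrow(ind)) {
    abort(sprintf("geno has %d columns but ind table has %d records.",
                  ncol(geno), nrow(ind)))
  }
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad)) abort("genotype dosages must be 0, 1, 2 or NA.")
  if (any(snp$physical_pos <= 0)) abort("physical positions must be positive.")
  if (any(snp$genetic_pos < 0)) abort("genetic positions must be >= 0.")
  if (any(snp$ref_allele == snp$alt_allele)) {
    abort("ref and alt alleles must differ.")
  }
  if (!"is_cpg_transition" %in% names(snp)) snp$is_cpg_transition <- FALSE
  if (!"sex" %in% names(ind)) ind$sex <- "U"
  if (!"udg" %in% names(ind)) ind$udg <- "half"
  if (!"ploidy" %in% names(ind)) {
    has_het <- apply(geno == 1L, 2, any, na.rm = TRUE)
    ind$ploidy <- ifelse(has_het, "diploid", "pseudo_haploid")
  }
  ph <- which(ind$ploidy == "pseudo_haploid")
  if (length(ph) && any(geno[, ph, drop = FALSE] == 1L, na.rm = TRUE)) {
    abort("pseudo-haploid samples must carry only dosages {0, 2, NA}.")
  }
  if (any(ind$group == "" | is.na(ind$group))) {
    abort("group labels must be non-empty.")
  }

  snp$block_id <- assign_blocks(snp$chromosome, snp$physical_pos, block_size)
  rownames(geno) <- snp$snp_id
  colnames(geno) <- ind$sample_id

  structure(
    list(geno = geno, snp = snp, ind = ind,
         block_size = block_size, provenance = provenance),
    class = "pf_dataset"
  )
}

# Contiguous physical windows per chromosome, numbered globally.
assign_blocks <- function(chromosome, physical_pos, block_size) {
  local <- floor((physical_pos - 1) / block_size)
  key <- paste(chromosome, local, sep = ":")
  as.integer(factor(key, levels = unique(key)))
}

#' @export
print.pf_dataset <- function(x, ...) {
  cat(sprintf(
    "<pf_dataset> %d SNPs x %d samples (%d groups, %d jackknife blocks)\n",
    nrow(x$geno), ncol(x$geno), dplyr::n_distinct(x$ind$group),
    max(x$snp$block_id)))
  ph <- sum(x$ind$ploidy == "pseudo_haploid")
  cat(sprintf("  pseudo-haploid samples: %d; missing calls: %.1f%%\n",
              ph, 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.pf_dataset <- function(x) dim(x$geno)

#' Subset a genotype dataset
#'
#' @param x A `pf_dataset`.
#' @param snps Logical or integer index over SNPs (rows).
#' @param samples Logical or integer index over samples, or sample ids.
#' @return A `pf_dataset` restricted to the selection; block ids are kept as
#'   assigned at construction so jackknife windows stay comparable.
#' @export
subset_dataset <- function(x, snps = NULL, samples = NULL) {
  stopifnot(inherits(x, "pf_dataset"))
  if (is.null(snps)) snps <- seq_len(nrow(x$geno))
  if (is.null(samples)) samples <- seq_len(ncol(x$geno))
  if (is.character(samples)) samples <- match(samples, x$ind$sample_id)
  out <- x
  out$geno <- x$geno[snps, samples, drop = FALSE]
  out$snp <- x$snp[snps, , drop = FALSE]
  out$ind <- x$ind[samples, , drop = FALSE]
  out
}

#' Drop transition SNPs at CpG sites
#'
#' Admixture-graph analyses on ancient DNA conventionally exclude CpG
#' transitions, where residual deamination damage is concentrated.
#'
#' @param dataset A `pf_dataset` whose SNP table has `is_cpg_transition`.
#' @return The dataset without flagged SNPs.
#' @export
drop_cpg_transitions <- function(dataset) {
  subset_dataset(dataset, snps = !dataset$snp$is_cpg_transition)
}
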