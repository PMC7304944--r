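#' Read an EIGENSTRAT genotype triple
#'
#' Reads the plain-ASCII geno/snp/ind triple that is the exchange standard
#' for ancient-DNA genotype data: one geno row per SNP with one character
#' per sample (`0`/`1`/`2` alternative-allele dosage, `9` missing), a
#' six-column `.snp` table (id, chromosome, genetic position in Morgans,
#' physical position, ref, alt) and a three-column `.ind` table (id, sex,
#' group label).
#'
#' @param geno_path,snp_path,ind_path Paths to the three files.
#' @param ploidy Either `"infer"` (samples with any heterozygous call are
#'   diploid, the rest pseudo-haploid) or a character vector over samples.
#' @param block_size Jackknife window size in bp (default 5 Mb).
#' @return A [genotype_dataset()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path,
                            ploidy = "infer", block_size = 5e6) {
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  snp_cols <- c("snp_id", "chromosome", "genetic_pos", "physical_pos",
                "ref_allele", "alt_allele")
  snp_raw <- if (length(readLines(snp_path, n = 1)) == 0) {
    stats::setNames(data.frame(character(0), character(0), numeric(0),
                               integer(0), character(0), character(0)),
                    snp_cols)
  } else {
    utils::read.table(snp_path, header = FALSE, col.names = snp_cols,
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  }
  ind_raw <- utils::read.table(ind_path, header = FALSE,
                               col.names = c("sample_id", "sex", "group"),
                               colClasses = "character")
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp_raw)) {
    abort(sprintf(
      "%s has %d rows but %s lists %d SNPs.",
      geno_path, length(lines), snp_path, nrow(snp_raw)))
  }
  nsamp <- nrow(ind_raw)
  widths <- nchar(lines)
  if (any(widths != nsamp)) {
    i <- which(widths != nsamp)[1]
    abort(sprintf("%s line %d has %d characters but %s lists %d samples.",
                  geno_path, i, widths[i], ind_path, nsamp))
  }
  chars <- matrix(as.character(unlist(strsplit(lines, "", fixed = TRUE),
                                      use.names = FALSE)),
                  nrow = length(lines), ncol = nsamp, byrow = TRUE)
  ok <- chars %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("%s: unknown genotype character '%s' at SNP row %d.",
                  geno_path, chars[i], (i - 1) %% nrow(chars) + 1))
  }
  geno <- matrix(as.integer(chars), nrow = nrow(chars), ncol = nsamp)
  geno[geno == 9L] <- NA_integer_

  ind <- tibble::as_tibble(ind_raw)
  if (!identical(ploidy, "infer")) {
    stopifnot(length(ploidy) == nsamp)
    ind$ploidy <- ploidy
  }
  genotype_dataset(geno, snp_raw, ind, block_size = block_size,
                   provenance = sprintf("read_eigenstrat(%s)", geno_path))
}

#' Write an EIGENSTRAT genotype triple
#'
#' Missing calls are written as `9`; pseudo-haploid samples therefore emit
#' only the characters `0`, `2`, `9`. Writing and re-reading a dataset
#' reproduces the genotype characters bit-exactly.
#'
#' @param dataset A `pf_dataset`.
#' @param geno_path,snp_path,ind_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_eigenstrat <- function(dataset, geno_path, snp_path, ind_path) {
  stopifnot(inherits(dataset, "pf_dataset"))
  g <- dataset$geno
  g[is.na(g)] <- 9L
  lines <- if (nrow(g) == 0) character(0) else
    apply(g, 1, function(r) paste(r, collapse = ""))
  writeLines(lines, geno_path)
  snp <- dataset$snp
  utils::write.table(
    data.frame(snp$snp_id, snp$chromosome,
               format(snp$genetic_pos, digits = 10, scientific = FALSE,
                      trim = TRUE),
               snp$physical_pos, snp$ref_allele, snp$alt_allele),
    snp_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(dataset$ind$sample_id, dataset$ind$sex, dataset$ind$group),
    ind_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(c(geno_path, snp_path, ind_path))
}
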