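# Shared fixtures, built in code at test time.

# A tiny handmade dataset: 4 SNPs x 3 samples on 2 chromosomes.
toy_dataset <- function() {
  geno <- matrix(c(
    0L, 2L, 1L,
    2L, NA, 1L,
    0L, 0L, 2L,
    NA, 2L, 0L
  ), nrow = 4, byrow = TRUE)
  snp <- tibble::tibble(
    snp_id = paste0("rs", 1:4),
    chromosome = c("1", "1", "2", "2"),
    genetic_pos = c(0.01, 0.02, 0.01, 0.03),
    physical_pos = c(1e6, 7e6, 2e6, 9e6),
    ref_allele = "A", alt_allele = "G"
  )
  ind <- tibble::tibble(
    sample_id = c("anc1", "anc2", "mod1"),
    group = c("Ancients", "Ancients", "Moderns"),
    sex = c("M", "F", "M"),
    ploidy = c("pseudo_haploid", "pseudo_haploid", "diploid"),
    udg = "half"
  )
  genotype_dataset(geno, snp, ind)
}

# Frequencies object built directly from given per-group frequency columns
# (one pseudo-haploid "sample" per group => p in {0, 1} impossible to fake,
# so build the pf_freqs structure explicitly with m copies per group).
manual_freqs <- function(p, m = NULL, block = NULL, inbreed = FALSE) {
  p <- as.matrix(p)
  if (is.null(m)) m <- matrix(1e9, nrow(p), ncol(p), dimnames = dimnames(p))
  if (is.null(block)) block <- rep(1:2, length.out = nrow(p))
  structure(
    list(count = p * m, m = m, p = p, block = block,
         snp = NULL, groups = colnames(p), inbreed = inbreed),
    class = "pf_freqs"
  )
}

# Simulated dataset from the bundled 8-leaf graph, cached per test file.
fixture_env <- new.env(parent = emptyenv())
fixture_dataset <- function(n_snps = 20000, n_samples = 6, seed = 7) {
  key <- paste("fix", n_snps, n_samples, seed, sep = "_")
  if (is.null(fixture_env[[key]])) {
    g <- example_graph()
    fr <- simulate_frequencies(g, n_snps, seed = seed)
    ds <- sample_dataset(
      fr,
      tibble::tibble(leaf = g$leaves, n_samples = n_samples,
                     ploidy = "pseudo_haploid", missing_rate = 0.05),
      seed = seed + 1)
    fixture_env[[key]] <- list(graph = g, freqsim = fr, dataset = ds,
                               freqs = group_freqs(ds, inbreed = TRUE))
  }
  fixture_env[[key]]
}

# Naive per-SNP loop oracles, independent of the vectorized implementation.
naive_f2 <- function(freqs, A, B, correction = TRUE) {
  vals <- numeric(0)
  for (s in seq_len(nrow(freqs$p))) {
    pa <- freqs$p[s, A]; pb <- freqs$p[s, B]
    ma <- freqs$m[s, A]; mb <- freqs$m[s, B]
    if (is.na(pa) || is.na(pb)) next
    v <- (pa - pb)^2
    if (correction) {
      if (ma >= 2) v <- v - pa * (1 - pa) / (ma - 1)
      if (mb >= 2) v <- v - pb * (1 - pb) / (mb - 1)
    }
    vals <- c(vals, v)
  }
  mean(vals)
}

naive_f3 <- function(freqs, C, A, B, correction = TRUE) {
  vals <- numeric(0)
  for (s in seq_len(nrow(freqs$p))) {
    pc <- freqs$p[s, C]; pa <- freqs$p[s, A]; pb <- freqs$p[s, B]
    mc <- freqs$m[s, C]
    if (is.na(pc) || is.na(pa) || is.na(pb)) next
    v <- (pc - pa) * (pc - pb)
    if (correction && mc >= 2) v <- v - pc * (1 - pc) / (mc - 1)
    vals <- c(vals, v)
  }
  mean(vals)
}

naive_f4 <- function(freqs, A, B, X, Y) {
  vals <- numeric(0)
  for (s in seq_len(nrow(freqs$p))) {
    pa <- freqs$p[s, A]; pb <- freqs$p[s, B]
    px <- freqs$p[s, X]; py <- freqs$p[s, Y]
    if (anyNA(c(pa, pb, px, py))) next
    vals <- c(vals, (pa - pb) * (px - py))
  }
  mean(vals)
}

# Random frequency table for oracle-equivalence checks.
random_freqs <- function(n_snps = 50, groups = paste0("G", 1:6), seed = 1,
                         missing_rate = 0.05) {
  withr::with_seed(seed, {
    p <- matrix(runif(n_snps * length(groups)), n_snps,
                dimnames = list(NULL, groups))
    m <- matrix(sample(2:20, n_snps * length(groups), replace = TRUE),
                n_snps, dimnames = list(NULL, groups))
    drop <- matrix(runif(n_snps * length(groups)) < missing_rate, n_snps)
    p[drop] <- NA
    m[drop] <- 0
    manual_freqs(p, m, block = rep(1:5, length.out = n_snps))
  })
}
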