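#' Simulate allele frequencies along an admixture graph
#'
#' Per-SNP ancestral frequencies are drawn from `freq_law`; along every
#' drift edge of length `f2_e` the child frequency is Beta-distributed
#' (Balding-Nichols parameterization) with mean equal to the parent
#' frequency and variance `f2_e * p0 * (1 - p0)`, where `p0` is the SNP's
#' ancestral frequency; at admixture nodes the child frequency is the
#' weight-averaged mixture `alpha * pA + (1 - alpha) * pB`. Anchoring the
#' drift variance to the ancestral heterozygosity makes every expected
#' f-statistic an exact linear function of branch lengths (see
#' [expected_fstats()]), not a small-drift approximation. Deterministic
#' given `seed`.
#'
#' @param graph A [pf_graph()].
#' @param n_snps Number of independent SNPs.
#' @param freq_law `"uniform"` or `"beta"` for the ancestral frequency.
#' @param freq_params Parameters of the law: `c(min, max)` for uniform,
#'   `c(shape1, shape2)` for Beta.
#' @param seed Integer seed.
#' @return An object of class `pf_freqsim`: list with `p` (SNPs x nodes
#'   frequency matrix, all nodes retained), `p0`, `graph`, `het`
#'   (analytic `E[p0 (1 - p0)]` of the law) and the law description.
#' @export
simulate_frequencies <- function(graph, n_snps, freq_law = "uniform",
                                 freq_params = c(0.1, 0.9), seed = 1L) {
  stopifnot(inherits(graph, "pf_graph"), n_snps >= 1)
  freq_law <- match.arg(freq_law, c("uniform", "beta"))
  with_seed(seed, {
    p0 <- switch(freq_law,
      uniform = runif(n_snps, freq_params[1], freq_params[2]),
      beta = rbeta(n_snps, freq_params[1], freq_params[2])
    )
    var_unit <- p0 * (1 - p0)
    p <- matrix(NA_real_, n_snps, length(graph$nodes),
                dimnames = list(NULL, graph$nodes))
    p[, graph$root] <- p0
    achild <- graph$admix$child
    for (v in graph$topo[-1]) {
      ei <- which(graph$drift$child == v)
      if (length(ei) == 1L) {
        mu <- p[, graph$drift$parent[ei]]
        len <- graph$drift$length[ei]
        if (len == 0) {
          p[, v] <- mu
        } else {
          mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
          v_tgt <- pmin(len * var_unit, 0.95 * mu * (1 - mu))
          fix <- v_tgt <= 0 # monomorphic ancestral sites do not drift
          v_tgt[fix] <- 1e-12
          k <- mu * (1 - mu) / v_tgt - 1
          draw <- rbeta(n_snps, mu * k, (1 - mu) * k)
          p[, v] <- ifelse(fix, mu, draw)
        }
      } else {
        ai <- which(achild == v)
        a <- graph$admix$alpha[ai]
        p[, v] <- a * p[, graph$admix$parentA[ai]] +
          (1 - a) * p[, graph$admix$parentB[ai]]
      }
    }
  })
  structure(list(p = p, p0 = p0, graph = graph,
                 het = ancestral_het(freq_law, freq_params),
                 freq_law = freq_law, freq_params = freq_params,
                 seed = seed),
            class = "pf_freqsim")
}

#' Mean ancestral heterozygosity of a frequency law
#'
#' Analytic `E[p (1 - p)]` for the supported ancestral-frequency laws;
#' the scale factor linking graph branch units to measured f-statistics.
#'
#' @param freq_law `"uniform"` or `"beta"`.
#' @param freq_params Law parameters as in [simulate_frequencies()].
#' @return A single number.
#' @export
ancestral_het <- function(freq_law = "uniform", freq_params = c(0.1, 0.9)) {
  freq_law <- match.arg(freq_law, c("uniform", "beta"))
  if (freq_law == "uniform") {
    a <- freq_params[1]; b <- freq_params[2]
    (a + b) / 2 - (a^2 + a * b + b^2) / 3
  } else {
    a <- freq_params[1]; b <- freq_params[2]
    ep <- a / (a + b)
    ep2 <- a * (a + 1) / ((a + b) * (a + b + 1))
    ep - ep2
  }
}

#' Sample a genotype dataset from simulated leaf frequencies
#'
#' Diploid samples draw `Binomial(2, p)` dosages; pseudo-haploid samples
#' draw a single allele (`Bernoulli(p)`, stored as dosage 0 or 2).
#' Missingness is applied independently per call. SNPs are laid out evenly
#' over chromosomes with a constant recombination map (genetic position
#' linear in physical position) and 5-Mb jackknife blocks.
#'
#' @param freqs A `pf_freqsim` from [simulate_frequencies()].
#' @param leaf_sampling Data frame with columns `leaf`, `n_samples`,
#'   `ploidy` (`"diploid"`/`"pseudo_haploid"`), `missing_rate`; defaults to
#'   4 pseudo-haploid samples per leaf with 5% missingness.
#' @param n_chromosomes,chromosome_morgans,chromosome_bp Map layout.
#' @param seed Integer seed.
#' @return A [genotype_dataset()] whose group labels are the leaf names.
#' @export
sample_dataset <- function(freqs, leaf_sampling = NULL,
                           n_chromosomes = 10, chromosome_morgans = 1,
                           chromosome_bp = 1e8, seed = 1L) {
  stopifnot(inherits(freqs, "pf_freqsim"))
  graph <- freqs$graph
  if (is.null(leaf_sampling)) {
    leaf_sampling <- tibble::tibble(leaf = graph$leaves, n_samples = 4,
                                    ploidy = "pseudo_haploid",
                                    missing_rate = 0.05)
  }
  leaf_sampling <- tibble::as_tibble(leaf_sampling)
  missing_col <- if ("missing_rate" %in% names(leaf_sampling)) {
    leaf_sampling$missing_rate
  } else {
    rep(0, nrow(leaf_sampling))
  }
  n_snps <- nrow(freqs$p)
  n_tot <- sum(leaf_sampling$n_samples)

  with_seed(seed, {
    chrom <- rep(seq_len(n_chromosomes), length.out = n_snps)
    chrom <- sort(chrom)
    pos <- integer(n_snps)
    for (cc in seq_len(n_chromosomes)) {
      idx <- which(chrom == cc)
      pos[idx] <- sort(sample.int(chromosome_bp, length(idx)))
    }
    snp <- tibble::tibble(
      snp_id = paste0("snp", seq_len(n_snps)),
      chromosome = as.character(chrom),
      genetic_pos = pos / chromosome_bp * chromosome_morgans,
      physical_pos = pos,
      ref_allele = "A", alt_allele = "G"
    )
    geno <- matrix(NA_integer_, n_snps, n_tot)
    ids <- character(n_tot)
    groups <- character(n_tot)
    ploidy <- character(n_tot)
    col <- 0L
    for (i in seq_len(nrow(leaf_sampling))) {
      leaf <- leaf_sampling$leaf[i]
      p <- freqs$p[, leaf]
      for (k in seq_len(leaf_sampling$n_samples[i])) {
        col <- col + 1L
        dos <- if (leaf_sampling$ploidy[i] == "diploid") {
          rbinom(n_snps, 2L, p)
        } else {
          2L * rbinom(n_snps, 1L, p)
        }
        if (missing_col[i] > 0) {
          dos[runif(n_snps) < missing_col[i]] <- NA_integer_
        }
        geno[, col] <- dos
        ids[col] <- sprintf("%s_%d", leaf, k)
        groups[col] <- leaf
        ploidy[col] <- leaf_sampling$ploidy[i]
      }
    }
  })
  genotype_dataset(
    geno, snp,
    tibble::tibble(sample_id = ids, group = groups, sex = "U",
                   ploidy = ploidy, udg = "half"),
    provenance = sprintf("sample_dataset(seed=%d)", seed)
  )
}

#' Simulate admixed haplotypes with exponential ancestry tracts
#'
#' Each target haplotype is a mosaic of ancestry segments: segment lengths
#' are exponential with mean `1/g` Morgans (`g` generations since the
#' admixture pulse), each segment's source is drawn independently with
#' probability `mixture_fraction` for source A, and alleles are drawn from
#' the segment's source frequency. The generating truth (per-segment table
#' and per-site ancestry) is returned alongside the haplotypes so that
#' dating methods can be validated by parameter recovery.
#'
#' @param g_generations Generations since admixture (`>= 1`).
#' @param mixture_fraction Probability a segment derives from source A.
#' @param n_haplotypes Number of target haplotypes.
#' @param freq_a,freq_b Per-SNP frequencies of the two source populations
#'   (vectors over the SNPs of `map`).
#' @param map Data frame with columns `chromosome` and `genetic_pos`
#'   (Morgans, non-decreasing within chromosome).
#' @param seed Integer seed.
#' @return List with `haplotypes` (haplotypes x SNPs 0/1 allele matrix),
#'   `ancestry` (logical matrix, `TRUE` where source A), and `segments`
#'   (tibble: `haplotype`, `chromosome`, `start`, `end`, `source`), with
#'   segment bounds in Morgans as generated (before truncation-merging).
#' @export
simulate_admixture_tracts <- function(g_generations, mixture_fraction,
                                      n_haplotypes, freq_a, freq_b, map,
                                      seed = 1L) {
  stopifnot(g_generations >= 1, mixture_fraction >= 0, mixture_fraction <= 1)
  map <- tibble::as_tibble(map)
  n_snps <- nrow(map)
  stopifnot(length(freq_a) == n_snps, length(freq_b) == n_snps)
  chroms <- unique(map$chromosome)

  hap <- matrix(0L, n_haplotypes, n_snps)
  anc <- matrix(FALSE, n_haplotypes, n_snps)
  seg_list <- list()
  with_seed(seed, {
    for (cc in chroms) {
      idx <- which(map$chromosome == cc)
      d <- map$genetic_pos[idx]
      len <- max(d)
      for (h in seq_len(n_haplotypes)) {
        # breakpoints of a Poisson(g) recombination process along the map
        n_exp <- ceiling(len * g_generations + 10 * sqrt(len * g_generations) + 10)
        gaps <- rexp(n_exp, rate = g_generations)
        while (sum(gaps) < len) gaps <- c(gaps, rexp(n_exp, g_generations))
        ends <- cumsum(gaps)
        n_seg <- which(ends >= len)[1]
        starts <- c(0, ends[seq_len(n_seg - 1)])
        ends <- pmin(ends[seq_len(n_seg)], len)
        src_a <- runif(n_seg) < mixture_fraction
        seg_of_snp <- findInterval(d, starts, left.open = FALSE)
        a <- src_a[seg_of_snp]
        p <- ifelse(a, freq_a[idx], freq_b[idx])
        hap[h, idx] <- rbinom(length(idx), 1L, p)
        anc[h, idx] <- a
        seg_list[[length(seg_list) + 1]] <- tibble::tibble(
          haplotype = h, chromosome = cc,
          start = starts, end = ends, source = ifelse(src_a, "A", "B"))
      }
    }
  })
  list(haplotypes = hap, ancestry = anc,
       segments = dplyr::bind_rows(seg_list))
}
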