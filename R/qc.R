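#' Filter SNPs by call-rate across samples
#'
#' Retains exactly those sites whose fraction of non-missing calls is at
#' least `min_called_fraction` (the conventional `geno 0.7` filter keeps
#' sites called in at least 70% of samples). The sample list is unchanged
#' and the operation is idempotent.
#'
#' @param dataset A `pf_dataset`.
#' @param min_called_fraction Minimum fraction of samples with a call,
#'   in `[0, 1]`.
#' @return The filtered `pf_dataset`.
#' @export
site_missingness_filter <- function(dataset, min_called_fraction = 0.7) {
  stopifnot(inherits(dataset, "pf_dataset"))
  stopifnot_scalar_number(min_called_fraction, "min_called_fraction", 0, 1)
  called <- rowMeans(!is.na(dataset$geno))
  subset_dataset(dataset, snps = called >= min_called_fraction)
}

#' Convert diploid calls to pseudo-haploid calls
#'
#' Emulates single-read genotyping: at heterozygous sites one of the two
#' alleles is chosen with equal probability and stored as a homozygous
#' dosage (`0` or `2`); homozygous and missing calls are unchanged.
#' Deterministic given `seed`.
#'
#' @param dataset A `pf_dataset`.
#' @param samples Samples to convert (ids or index); default all.
#' @param seed Integer seed for the allele draws.
#' @return A `pf_dataset` in which the converted samples are marked
#'   `pseudo_haploid`.
#' @export
pseudo_haploidize <- function(dataset, samples = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "pf_dataset"))
  if (is.null(samples)) samples <- seq_len(ncol(dataset$geno))
  if (is.character(samples)) samples <- match(samples, dataset$ind$sample_id)
  g <- dataset$geno[, samples, drop = FALSE]
  het <- which(g == 1L)
  with_seed(seed, {
    g[het] <- 2L * rbinom(length(het), 1L, 0.5)
  })
  out <- dataset
  out$geno[, samples] <- g
  out$ind$ploidy[samples] <- "pseudo_haploid"
  out
}

#' Authenticity gate for ancient samples
#'
#' Applies the standard ancient-DNA authenticity thresholds to a per-sample
#' QC table: partially UDG-treated ("half") libraries must retain a terminal
#' C-to-T damage rate strictly above 3% (10% for untreated "minus"
#' libraries) to be accepted as authentic; contamination point estimates
#' must be strictly below 5% (mtDNA), 3% (X chromosome, evaluated in males
#' only, where hemizygosity makes the estimate possible) and 5%
#' (genome-wide). Absent metrics are not evaluated. Decisions depend only
#' on the QC fields, sex and UDG treatment.
#'
#' @param samples Data frame with columns `sample_id`, and optionally `sex`
#'   (`"M"`/`"F"`/`"U"`), `udg` (`"half"`, `"minus"`, `"plus"`),
#'   `damage_rate`, `mt_contamination`, `x_contamination`,
#'   `autosomal_contamination` (fractions in `[0, 1]`, `NA` when not
#'   measured).
#' @return A tibble with `sample_id`, `pass` and `reasons` (all violated
#'   rules, `;`-separated; empty string when passing).
#' @export
qc_gate <- function(samples) {
  samples <- tibble::as_tibble(samples)
  stopifnot("sample_id" %in% names(samples))
  n <- nrow(samples)
  get <- function(col, default) {
    if (col %in% names(samples)) samples[[col]] else rep(default, n)
  }
  sex <- get("sex", "U")
  udg <- get("udg", "half")
  dmg <- get("damage_rate", NA_real_)
  mt <- get("mt_contamination", NA_real_)
  xc <- get("x_contamination", NA_real_)
  au <- get("autosomal_contamination", NA_real_)
  for (v in list(dmg, mt, xc, au)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort("QC metric fractions must lie in [0, 1].")
    }
  }

  reasons <- vector("list", n)
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  add(!is.na(dmg) & udg == "half" & dmg <= 0.03,
      "terminal damage <= 3% (UDG-half)")
  add(!is.na(dmg) & udg == "minus" & dmg <= 0.10,
      "terminal damage <= 10% (UDG-minus)")
  add(!is.na(mt) & mt >= 0.05, "mtDNA contamination >= 5%")
  add(!is.na(xc) & sex == "M" & xc >= 0.03, "X contamination >= 3%")
  add(!is.na(au) & au >= 0.05, "autosomal contamination >= 5%")

  tibble::tibble(
    sample_id = samples$sample_id,
    pass = lengths(reasons) == 0,
    reasons = vapply(reasons, function(r) paste(r, collapse = "; "), "")
  )
}

#' Age label for a genetic group, in years BP
#'
#' The age component of a `Country_SiteName_AgeBP` group label: the mean
#' calibrated date (midpoint of the calibrated range) is averaged over the
#' directly dated members and rounded to the closest century; members
#' without a direct date inherit the group value and are ignored in the
#' average. Midpoints exactly between two centuries round away from zero.
#'
#' @param member_dates Data frame with columns `older_bound`,
#'   `younger_bound` (years calBP, `older_bound >= younger_bound`) and
#'   `directly_dated` (logical).
#' @return The group age in years BP, a multiple of 100.
#' @export
group_age_label <- function(member_dates) {
  d <- tibble::as_tibble(member_dates)
  stopifnot(all(c("older_bound", "younger_bound", "directly_dated")
                %in% names(d)))
  if (any(d$older_bound < d$younger_bound, na.rm = TRUE)) {
    abort("older_bound must be >= younger_bound.")
  }
  d <- dplyr::filter(d, .data$directly_dated,
                     !is.na(.data$older_bound), !is.na(.data$younger_bound))
  if (nrow(d) == 0) abort("no directly dated member; cannot assign an age.")
  mid <- (d$older_bound + d$younger_bound) / 2
  m <- mean(mid)
  # round half away from zero at 50-year midpoints
  100 * sign(m) * floor(abs(m) / 100 + 0.5)
}

#' Pairwise mismatch rates and relatedness screen
#'
#' For every sample pair, the fraction of jointly called sites with unequal
#' dosage calls. On pseudo-haploid data, unrelated individuals from one
#' population share a characteristic background rate; duplicates and close
#' relatives fall well below it. Pairs whose rate is below
#' `(1 - relatedness_margin)` times the within-group background median are
#' flagged for manual review.
#'
#' @param dataset A `pf_dataset` with at least two samples.
#' @param min_overlap Minimum number of jointly called sites for a rate to
#'   be reported; pairs below it get `NA`.
#' @param relatedness_margin Fraction below the background median at which
#'   a pair is flagged (the decision threshold is a screening convention,
#'   not an estimate; it is configurable and reported).
#' @return A tibble with one row per unordered pair: `sample_1`,
#'   `sample_2`, `n_overlap`, `mismatch`, `flagged`, plus attributes
#'   `matrix` (full symmetric rate matrix, zero diagonal) and
#'   `background_median`.
#' @export
pairwise_mismatch <- function(dataset, min_overlap = 1L,
                              relatedness_margin = 0.25) {
  stopifnot(inherits(dataset, "pf_dataset"))
  g <- dataset$geno
  n <- ncol(g)
  if (n < 2) abort("need at least two samples.")
  called <- !is.na(g)
  gm <- g
  gm[!called] <- 0L
  # mismatch counts via dosage agreement: treat calls as categorical
  overlap <- crossprod(called * 1)
  match_cnt <- matrix(0, n, n)
  for (v in c(0L, 1L, 2L)) {
    iv <- (gm == v & called) * 1
    match_cnt <- match_cnt + crossprod(iv)
  }
  mm <- 1 - match_cnt / overlap
  mm[overlap < min_overlap] <- NA
  diag(mm) <- 0
  dimnames(mm) <- list(dataset$ind$sample_id, dataset$ind$sample_id)

  idx <- which(upper.tri(mm), arr.ind = TRUE)
  res <- tibble::tibble(
    sample_1 = dataset$ind$sample_id[idx[, 1]],
    sample_2 = dataset$ind$sample_id[idx[, 2]],
    group_1 = dataset$ind$group[idx[, 1]],
    group_2 = dataset$ind$group[idx[, 2]],
    n_overlap = overlap[idx],
    mismatch = mm[idx]
  )
  same <- res$group_1 == res$group_2
  bg <- if (any(same & !is.na(res$mismatch))) {
    median(res$mismatch[same], na.rm = TRUE)
  } else {
    median(res$mismatch, na.rm = TRUE)
  }
  res$flagged <- !is.na(res$mismatch) &
    res$mismatch < (1 - relatedness_margin) * bg
  attr(res, "matrix") <- mm
  attr(res, "background_median") <- bg
  res
}
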