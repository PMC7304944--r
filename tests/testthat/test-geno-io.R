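# EIGENSTRAT input/output, genotype filters, QC gate, grouping, kinship.

test_that("reading the documented toy triple transcribes the format", {
  dir <- withr::local_tempdir()
  writeLines(c("09", "21", "10"), file.path(dir, "toy.geno"))
  writeLines(c("rs1\t1\t0.01\t100\tA\tG",
               "rs2\t1\t0.02\t200\tA\tC",
               "rs3\t1\t0.03\t300\tT\tC"), file.path(dir, "toy.snp"))
  writeLines(c("s1\tM\tPop1", "s2\tF\tPop2"), file.path(dir, "toy.ind"))
  ds <- read_eigenstrat(file.path(dir, "toy.geno"), file.path(dir, "toy.snp"),
                        file.path(dir, "toy.ind"))
  # column per sample: s1 = (0, 2, 1), s2 = (NA, 1, 0)
  expect_identical(unname(ds$geno[, 1]), c(0L, 2L, 1L))
  expect_identical(unname(ds$geno[, 2]), c(NA_integer_, 1L, 0L))
  expect_equal(ds$snp$genetic_pos, c(0.01, 0.02, 0.03))
  expect_identical(ds$ind$sample_id, c("s1", "s2"))
})

test_that("write + read round trips a dataset bit-exactly", {
  ds <- fixture_dataset(n_snps = 500, n_samples = 2)$dataset
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("x.geno", "x.snp", "x.ind"))
  write_eigenstrat(ds, paths[1], paths[2], paths[3])
  back <- read_eigenstrat(paths[1], paths[2], paths[3])
  expect_identical(unname(back$geno), unname(ds$geno))
  expect_equal(back$snp$genetic_pos, ds$snp$genetic_pos)
  expect_identical(back$snp$snp_id, ds$snp$snp_id)
  expect_identical(back$ind$sample_id, ds$ind$sample_id)
  expect_identical(back$ind$group, ds$ind$group)
  # pseudo-haploid samples emit only 0/2/9 characters
  chars <- unique(strsplit(paste(readLines(paths[1]), collapse = ""), "")[[1]])
  expect_true(all(chars %in% c("0", "2", "9")))
  # second round trip is the identity on files
  write_eigenstrat(back, paths[1], paths[2], paths[3])
  back2 <- read_eigenstrat(paths[1], paths[2], paths[3])
  expect_identical(back2$geno, back$geno)
})

test_that("an empty dataset round trips to valid empty files", {
  ds <- suppressWarnings(genotype_dataset(
    matrix(integer(0), 0, 2),
    tibble::tibble(snp_id = character(0), chromosome = character(0),
                   genetic_pos = numeric(0), physical_pos = integer(0),
                   ref_allele = character(0), alt_allele = character(0)),
    tibble::tibble(sample_id = c("a", "b"), group = "G")))
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("e.geno", "e.snp", "e.ind"))
  write_eigenstrat(ds, paths[1], paths[2], paths[3])
  back <- read_eigenstrat(paths[1], paths[2], paths[3])
  expect_identical(dim(back$geno), c(0L, 2L))
})

test_that("malformed triples produce structured errors naming the file", {
  dir <- withr::local_tempdir()
  writeLines(c("09", "21", "10", "00"), file.path(dir, "bad.geno"))
  writeLines(c("rs1\t1\t0.01\t100\tA\tG",
               "rs2\t1\t0.02\t200\tA\tC",
               "rs3\t1\t0.03\t300\tT\tC"), file.path(dir, "bad.snp"))
  writeLines(c("s1\tM\tPop1", "s2\tF\tPop2"), file.path(dir, "bad.ind"))
  expect_error(
    read_eigenstrat(file.path(dir, "bad.geno"), file.path(dir, "bad.snp"),
                    file.path(dir, "bad.ind")),
    "bad.geno.*4 rows.*3")
  writeLines(c("09", "2x", "10"), file.path(dir, "bad.geno"))
  expect_error(
    read_eigenstrat(file.path(dir, "bad.geno"), file.path(dir, "bad.snp"),
                    file.path(dir, "bad.ind")),
    "unknown genotype character 'x'")
})

test_that("site missingness filter keeps sites called in enough samples", {
  # 10 samples; site 1 has 6 called (< 70%), site 2 has 7 called (>= 70%)
  geno <- rbind(c(rep(0L, 6), rep(NA, 4)),
                c(rep(2L, 7), rep(NA, 3)),
                rep(0L, 10))
  snp <- tibble::tibble(snp_id = paste0("s", 1:3), chromosome = "1",
                        genetic_pos = 1:3 / 100, physical_pos = 1:3 * 1e5,
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = paste0("i", 1:10), group = "G")
  ds <- genotype_dataset(geno, snp, ind)
  kept <- site_missingness_filter(ds, 0.7)
  expect_identical(kept$snp$snp_id, c("s2", "s3"))
  expect_identical(kept$ind, ds$ind)
  # idempotent
  expect_identical(site_missingness_filter(kept, 0.7)$geno, kept$geno)
  # degenerate thresholds
  expect_identical(site_missingness_filter(ds, 0)$snp$snp_id, ds$snp$snp_id)
  expect_identical(site_missingness_filter(ds, 1)$snp$snp_id, "s3")
})

test_that("pseudo-haploidization flips only heterozygous calls, seeded", {
  n <- 10000
  geno <- cbind(c(0L, 2L, NA, rep(1L, n)))
  snp <- tibble::tibble(snp_id = paste0("s", seq_len(n + 3)),
                        chromosome = "1",
                        genetic_pos = seq_len(n + 3) / 1e4,
                        physical_pos = seq_len(n + 3) * 100,
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = "d1", group = "G", ploidy = "diploid")
  ds <- genotype_dataset(geno, snp, ind)
  ph <- pseudo_haploidize(ds, seed = 42)
  expect_identical(unname(ph$geno[1:3, 1]), c(0L, 2L, NA))
  expect_true(all(ph$geno[-(1:3), 1] %in% c(0L, 2L)))
  expect_identical(ph$ind$ploidy, "pseudo_haploid")
  # deterministic given the seed
  expect_identical(pseudo_haploidize(ds, seed = 42)$geno, ph$geno)
  # binomial oracle: fraction mapped to 2 is 0.5 within 0.02
  frac2 <- mean(ph$geno[-(1:3), 1] == 2L)
  expect_lt(abs(frac2 - 0.5), 0.02)
})

test_that("authenticity gate applies the printed thresholds strictly", {
  tab <- tibble::tibble(
    sample_id = c("pass_male", "low_damage", "female_no_x", "contaminated",
                  "udg_minus_ok", "at_threshold"),
    sex = c("M", "M", "F", "M", "M", "M"),
    udg = c("half", "half", "half", "half", "minus", "half"),
    damage_rate = c(0.05, 0.025, 0.06, 0.08, 0.15, 0.03),
    mt_contamination = c(0.02, 0.01, 0.02, 0.06, NA, 0.05),
    x_contamination = c(0.02, NA, NA, 0.01, 0.01, 0.03),
    autosomal_contamination = c(0.01, 0.02, 0.04, 0.02, NA, 0.01)
  )
  res <- qc_gate(tab)
  expect_identical(res$pass,
                   c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_match(res$reasons[2], "damage")
  expect_match(res$reasons[4], "mtDNA")
  # boundary values fail on every rule they touch
  expect_match(res$reasons[6], "damage")
  expect_match(res$reasons[6], "mtDNA")
  expect_match(res$reasons[6], "X contamination")
  # decisions are a pure function of the QC fields: row order irrelevant
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  expect_identical(qc_gate(tab[perm, ])$pass, res$pass[perm])
})

test_that("x-contamination is only evaluated in males", {
  male <- qc_gate(tibble::tibble(sample_id = "m", sex = "M", udg = "half",
                                 damage_rate = 0.05, x_contamination = 0.04))
  female <- qc_gate(tibble::tibble(sample_id = "f", sex = "F", udg = "half",
                                   damage_rate = 0.05,
                                   x_contamination = 0.04))
  expect_false(male$pass)
  expect_true(female$pass)
})

test_that("group age labels average direct dates and round to centuries", {
  expect_equal(group_age_label(tibble::tibble(
    older_bound = 1700, younger_bound = 1565, directly_dated = TRUE)), 1600)
  expect_equal(group_age_label(tibble::tibble(
    older_bound = c(6780, 6960), younger_bound = c(6650, 6790),
    directly_dated = TRUE)), 6800)
  expect_equal(group_age_label(tibble::tibble(
    older_bound = c(1185, 1180), younger_bound = c(1010, 985),
    directly_dated = TRUE)), 1100)
  # undated members are ignored; order does not matter
  d <- tibble::tibble(older_bound = c(6780, 100, 6960),
                      younger_bound = c(6650, 50, 6790),
                      directly_dated = c(TRUE, FALSE, TRUE))
  expect_equal(group_age_label(d), 6800)
  expect_equal(group_age_label(d[c(3, 1, 2), ]), 6800)
  expect_error(group_age_label(tibble::tibble(
    older_bound = 100, younger_bound = 50, directly_dated = FALSE)),
    "directly dated")
})

test_that("pairwise mismatch detects duplicates and is symmetric", {
  n <- 2000
  withr::with_seed(9, {
    a <- 2L * rbinom(n, 1, 0.5)
    b <- 2L * rbinom(n, 1, 0.5)
    cc <- 2L * rbinom(n, 1, 0.5)
  })
  geno <- cbind(a, a, b, cc, 2L - b) # a duplicated; last opposite of b
  snp <- tibble::tibble(snp_id = paste0("s", 1:n), chromosome = "1",
                        genetic_pos = (1:n) / n, physical_pos = 1:n * 1000,
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = c("a1", "a2", "b", "c", "nb"),
                        group = "G", ploidy = "pseudo_haploid")
  ds <- genotype_dataset(geno, snp, ind)
  mm <- pairwise_mismatch(ds)
  m <- attr(mm, "matrix")
  expect_equal(unname(diag(m)), rep(0, 5))
  expect_identical(m, t(m))
  expect_equal(m["a1", "a2"], 0)
  expect_equal(m["b", "nb"], 1)
  dup <- mm[mm$sample_1 == "a1" & mm$sample_2 == "a2", ]
  expect_true(dup$flagged)
  # independent draws at freq 0.5 mismatch at rate 1/2 (analytic)
  expect_lt(abs(m["b", "c"] - 0.5), 3 * sqrt(0.25 / n))
  unrelated <- mm[mm$sample_1 == "b" & mm$sample_2 == "c", ]
  expect_false(unrelated$flagged)
})
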