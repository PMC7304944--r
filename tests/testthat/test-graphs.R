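# Expected f-statistics on graphs, GLS fitting, greedy search.

# Brute-force oracle: enumerate every root path of each leaf with its
# admixture weight; the frequency deviation of a leaf is the
# weight-average over its paths of the drift increments, so
# cov(i, j) = sum over path pairs of w_i w_j length(P_i intersect P_j)
# and f2(i, j) = cov(i,i) + cov(j,j) - 2 cov(i,j).
oracle_f2 <- function(g, i, j) {
  paths <- function(node) {
    de <- which(g$drift$child == node)
    if (length(de) == 1) {
      up <- paths(g$drift$parent[de])
      return(lapply(up, function(p) {
        list(edges = c(p$edges, de), w = p$w)
      }))
    }
    ae <- which(g$admix$child == node)
    if (length(ae) == 1) {
      pa <- paths(g$admix$parentA[ae])
      pb <- paths(g$admix$parentB[ae])
      return(c(
        lapply(pa, function(p) list(edges = p$edges,
                                    w = p$w * g$admix$alpha[ae])),
        lapply(pb, function(p) list(edges = p$edges,
                                    w = p$w * (1 - g$admix$alpha[ae])))))
    }
    list(list(edges = integer(0), w = 1)) # root
  }
  cv <- function(px, py) {
    tot <- 0
    for (a in px) {
      for (b in py) {
        tot <- tot + a$w * b$w * sum(g$drift$length[intersect(a$edges,
                                                              b$edges)])
      }
    }
    tot
  }
  pi_ <- paths(i); pj <- paths(j)
  cv(pi_, pi_) + cv(pj, pj) - 2 * cv(pi_, pj)
}

test_that("expected f2 matches path arithmetic on trees", {
  g <- pf_graph(tibble::tibble(parent = c("R", "R", "C", "C"),
                               child = c("C", "Out", "A", "B"),
                               length = c(0.03, 0.05, 0.01, 0.02)))
  f2 <- expected_fstats(g)
  expect_equal(f2["A", "B"], 0.01 + 0.02) # pendant sum
  expect_equal(f2["A", "Out"], 0.01 + 0.03 + 0.05)
  expect_error(
    pf_graph(tibble::tibble(parent = c("R", "A", "B"),
                            child = c("A", "B", "A"), length = 0.1)),
    "parent|cycle|root")
})

test_that("expected f-statistics equal the path-enumeration oracle", {
  g <- example_graph()
  f2 <- expected_fstats(g)
  for (i in g$leaves) {
    for (j in g$leaves) {
      expect_equal(f2[i, j], oracle_f2(g, i, j), tolerance = 1e-12)
    }
  }
})

test_that("expected f4 is linear in the admixture weight", {
  make <- function(alpha) pf_graph(
    tibble::tibble(parent = c("R", "R", "n", "a0", "n", "b0", "M"),
                   child = c("Out", "n", "a0", "A", "b0", "B", "Madm"),
                   length = c(0.05, 0.02, 0.03, 0, 0.03, 0, 0)),
    tibble::tibble(child = "M", parentA = "a0", parentB = "b0",
                   alpha = alpha))
  f4_at <- function(alpha) {
    f2 <- expected_fstats(make(alpha))
    expected_f4(f2, "A", "B", "Madm", "Out")
  }
  ends <- c(f4_at(0), f4_at(1))
  for (a in c(0.25, 0.5, 0.8)) {
    expect_equal(f4_at(a), ends[1] + a * (ends[2] - ends[1]),
                 tolerance = 1e-12)
  }
})

test_that("expected f3 goes negative for an even mixture of long branches", {
  g <- pf_graph(
    tibble::tibble(parent = c("R", "R", "n", "a0", "n", "b0", "M"),
                   child = c("Out", "n", "a0", "A", "b0", "B", "Madm"),
                   length = c(0.05, 0.02, 0.2, 0, 0.2, 0, 0.001)),
    tibble::tibble(child = "M", parentA = "a0", parentB = "b0",
                   alpha = 0.5))
  f2 <- expected_fstats(g)
  # closed form: f3 = pendant - alpha (1 - alpha) * f2(A, B)
  expect_equal(expected_f3(f2, "Madm", "A", "B"),
               0.001 - 0.25 * 0.4, tolerance = 1e-12)
  expect_lt(expected_f3(f2, "Madm", "A", "B"), 0)
})

test_that("f-statistic identities hold for the expected values", {
  f2 <- expected_fstats(example_graph())
  lv <- rownames(f2)
  expect_equal(f2, t(f2))
  # f4 additivity and the f3 half-sum identity
  expect_equal(
    expected_f4(f2, lv[1], lv[2], lv[3], lv[4]),
    expected_f4(f2, lv[1], lv[2], lv[3], lv[5]) +
      expected_f4(f2, lv[1], lv[2], lv[5], lv[4]),
    tolerance = 1e-12)
  expect_equal(expected_f3(f2, lv[3], lv[1], lv[2]),
               (f2[lv[3], lv[1]] + f2[lv[3], lv[2]] - f2[lv[1], lv[2]]) / 2,
               tolerance = 1e-14)
})

test_that("CpG-transition exclusion monotonically shrinks the SNP set", {
  ds <- toy_dataset()
  ds$snp$is_cpg_transition <- c(TRUE, FALSE, TRUE, FALSE)
  kept <- drop_cpg_transitions(ds)
  expect_identical(kept$snp$snp_id, c("rs2", "rs4"))
  expect_lte(nrow(drop_cpg_transitions(kept)$snp), nrow(kept$snp))
})

# Synthetic basis whose block means equal the expected statistics of a
# known graph exactly (perfect data).
perfect_basis <- function(g) {
  f2 <- expected_fstats(g)
  leaves <- g$leaves
  pairs <- utils::combn(length(leaves), 2)
  vals <- apply(pairs, 2, function(q) f2[leaves[q[1]], leaves[q[2]]])
  S <- outer(c(100, 100, 100), vals) # 3 equal blocks of 100 SNPs
  structure(
    list(groups = leaves, pairs = pairs,
         pair_names = paste(leaves[pairs[1, ]], leaves[pairs[2, ]],
                            sep = "|"),
         S = S, counts = rep(100, 3), n_snps = 300, n_blocks = 3,
         correction = TRUE),
    class = "pf_fbasis")
}

test_that("fitting perfect observations reproduces them exactly", {
  g <- pf_graph(tibble::tibble(
    parent = c("R", "R", "n", "n", "m", "m"),
    child = c("Out", "n", "A", "m", "B", "C"),
    length = c(0.05, 0.02, 0.03, 0.01, 0.02, 0.025)))
  fit <- fit_graph(g, basis = perfect_basis(g), n_restarts = 6, seed = 2)
  expect_lt(fit$objective, 1e-6)
  expect_equal(unname(expected_fstats(fit$graph)),
               unname(expected_fstats(g)), tolerance = 1e-5)
})

test_that("correct topologies fit and wrong topologies score badly", {
  fx <- fixture_dataset(n_snps = 20000, n_samples = 6)
  right_g <- pf_graph(tibble::tribble(
    ~parent, ~child, ~length,
    "R", "Outgroup", 0.08, "R", "anc1", 0.02,
    "anc1", "NorthAmerica", 0.04, "anc1", "anc3", 0.05,
    "anc3", "hsAnc", 0.03, "hsAnc", "HighlandsSouth", 0.01,
    "anc3", "csAnc", 0.03, "csAnc", "CoastSouth", 0.01,
    "Madm", "Admixed", 0.01),
    tibble::tibble(child = "Madm", parentA = "hsAnc", parentB = "csAnc",
                   alpha = 0.5))
  fit <- fit_graph(right_g, fx$freqs, n_restarts = 4, seed = 3)
  expect_lt(fit$worst_abs_z, 3)
  # forcing the admixed leaf into a clean clade with CoastSouth misfits
  wrong_g <- pf_graph(tibble::tribble(
    ~parent, ~child, ~length,
    "R", "Outgroup", 0.08, "R", "anc1", 0.02,
    "anc1", "NorthAmerica", 0.04, "anc1", "anc3", 0.05,
    "anc3", "HighlandsSouth", 0.04, "anc3", "cs0", 0.03,
    "cs0", "CoastSouth", 0.01, "cs0", "Admixed", 0.01))
  fitw <- fit_graph(wrong_g, fx$freqs, n_restarts = 4, seed = 3)
  expect_gt(fitw$worst_abs_z, 3)
  # a true extra parameter cannot worsen the objective
  expect_lte(fit$objective, fitw$objective + 1e-6)
})

greedy_truth <- function(alpha = 0.4) {
  pf_graph(tibble::tribble(
    ~parent, ~child, ~length,
    "R", "O", 0.06, "R", "n1", 0.02,
    "n1", "na", 0.035, "na", "A", 0.005,
    "n1", "nb", 0.035, "nb", "B", 0.005,
    "mix", "M", 0.01),
    tibble::tibble(child = "mix", parentA = "na", parentB = "nb",
                   alpha = alpha))
}

greedy_freqs <- function(seed, n_snps = 15000, n_samples = 6) {
  g <- greedy_truth()
  fr <- simulate_frequencies(g, n_snps, seed = seed)
  ds <- sample_dataset(fr, tibble::tibble(leaf = g$leaves,
                                          n_samples = n_samples,
                                          ploidy = "pseudo_haploid",
                                          missing_rate = 0.05),
                       seed = seed + 1)
  group_freqs(ds, inbreed = TRUE)
}

test_that("greedy addition enumerates E + E(E-1)/2 candidates", {
  fq <- greedy_freqs(seed = 111, n_snps = 4000, n_samples = 4)
  base_g <- pf_graph(tibble::tibble(parent = c("R", "R", "n", "n"),
                                    child = c("O", "n", "A", "B"),
                                    length = c(0.06, 0.02, 0.04, 0.04)))
  step <- greedy_add_population(base_g, "M", fq, n_restarts = 2, seed = 5)
  E <- 4
  expect_equal(nrow(step$ledger), E + E * (E - 1) / 2)
  expect_equal(sum(step$ledger$type == "simple"), E)
  # with admixture disallowed, only simple attachments are proposed
  step0 <- greedy_add_population(base_g, "M", fq, allow_admixture = FALSE,
                                 n_restarts = 2, seed = 5)
  expect_equal(nrow(step0$ledger), E)
  expect_true(all(step0$ledger$type == "simple"))
})

test_that("a clean clade attaches unadmixed on its sister's pendant edge", {
  tree <- pf_graph(tibble::tribble(
    ~parent, ~child, ~length,
    "R", "O", 0.06, "R", "n1", 0.02,
    "n1", "A", 0.04, "n1", "n2", 0.02,
    "n2", "B", 0.02, "n2", "C", 0.025))
  fr <- simulate_frequencies(tree, 15000, seed = 121)
  ds <- sample_dataset(fr, tibble::tibble(leaf = tree$leaves, n_samples = 6,
                                          ploidy = "pseudo_haploid",
                                          missing_rate = 0.05), seed = 122)
  fq <- group_freqs(ds, inbreed = TRUE)
  base_g <- pf_graph(tibble::tibble(parent = c("R", "R", "n1", "n1"),
                                    child = c("O", "n1", "A", "B"),
                                    length = c(0.06, 0.02, 0.04, 0.04)))
  step <- greedy_add_population(base_g, "C", fq, n_restarts = 3, seed = 7)
  expect_identical(step$ledger$type[step$winner], "simple")
  expect_identical(step$ledger$attachment[step$winner], "n1->B")
  expect_lt(step$fit$worst_abs_z, 3)
})

test_that("an admixed population attaches with its weight recovered", {
  fq <- greedy_freqs(seed = 123)
  base_g <- pf_graph(tibble::tibble(parent = c("R", "R", "n1", "n1"),
                                    child = c("O", "n1", "A", "B"),
                                    length = c(0.06, 0.02, 0.04, 0.04)))
  step <- greedy_add_population(base_g, "M", fq, n_restarts = 3, seed = 7)
  expect_identical(step$ledger$type[step$winner], "admixed")
  # the admixture joins the A-side and B-side lineages
  att <- step$ledger$attachment[step$winner]
  expect_match(att, "n1->A")
  expect_match(att, "n1->B")
  # same solve as the winning candidate, now with jackknife errors
  refit <- fit_graph(step$fit$graph, basis = paleoflow:::fstat_basis(
    fq, c(base_g$leaves, "M")), n_restarts = 3,
    seed = 7 + step$winner, se_method = "jackknife")
  a <- refit$graph$admix$alpha
  se <- refit$par_se$se[startsWith(refit$par_se$parameter, "alpha")]
  # alpha belongs to parentA; orient against the truth via the drift chain
  chain <- function(g, leaf) {
    out <- character(0); v <- leaf
    repeat {
      de <- which(g$drift$child == v)
      if (!length(de)) break
      v <- g$drift$parent[de]
      out <- c(out, v)
    }
    out
  }
  truth <- if (refit$graph$admix$parentA %in%
                 chain(refit$graph, "A")) 0.4 else 0.6
  expect_lt(abs(a - truth), 2 * se + 1e-8)
})

test_that("greedy search recovers topology and respects the admixture cap", {
  fq <- greedy_freqs(seed = 131)
  skeleton <- pf_graph(tibble::tibble(parent = c("R", "R"),
                                      child = c("O", "A"),
                                      length = c(0.06, 0.06)))
  out <- greedy_search(skeleton, c("B", "M"), fq, max_admixtures = 1,
                       n_restarts = 3, seed = 9)
  final <- out$final
  expect_length(out$fits, 2)
  expect_lt(final$worst_abs_z, 3)
  expect_equal(nrow(final$graph$admix), 1) # M admixed, and only M
  expect_identical(final$graph$admix$child, "M_mix")
  # unrooted splits (ignoring the admixed leaf) match the truth
  expect_identical(
    paleoflow:::graph_splits(final$graph, drop_leaves = "M"),
    paleoflow:::graph_splits(greedy_truth(), drop_leaves = "M"))
  # with the cap exhausted no admixed attachment is allowed
  out0 <- greedy_search(skeleton, c("B"), fq, max_admixtures = 0,
                        n_restarts = 2, seed = 9)
  expect_true(all(out0$ledgers[[1]]$type == "simple"))
  # adding zero populations returns the skeleton fit unchanged
  g3 <- pf_graph(tibble::tibble(parent = c("R", "R", "n", "n"),
                                child = c("O", "n", "A", "B"),
                                length = c(0.06, 0.02, 0.04, 0.04)))
  out_null <- greedy_search(g3, character(0), fq, n_restarts = 2, seed = 9)
  expect_identical(out_null$final$graph$leaves, g3$leaves)
})
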