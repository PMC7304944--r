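# Admixture-graph fitting: generalized least squares on basis f3
# statistics, residual Z-scores over every f2/f3/f4 of the fitted leaves,
# and the greedy population-addition search.

graph_par_get <- function(graph) {
  c(graph$drift$length, graph$admix$alpha)
}

graph_par_set <- function(graph, par) {
  ne <- nrow(graph$drift)
  graph$drift$length <- pmax(par[seq_len(ne)], 0)
  if (nrow(graph$admix)) {
    graph$admix$alpha <- pmin(pmax(par[ne + seq_len(nrow(graph$admix))], 0), 1)
  }
  graph
}

# Residual table of observed vs expected f2/f3/f4 over the graph leaves.
graph_residuals <- function(graph, basis, base) {
  leaves <- graph$leaves
  others <- setdiff(leaves, base)
  combos <- list()
  labels <- list()
  add <- function(v, kind, pops) {
    combos[[length(combos) + 1]] <<- v
    labels[[length(labels) + 1]] <<-
      tibble::tibble(kind = kind,
                     pop1 = pops[1], pop2 = pops[2],
                     pop3 = pops[3] %||% NA_character_,
                     pop4 = pops[4] %||% NA_character_)
  }
  prs <- utils::combn(leaves, 2)
  for (q in seq_len(ncol(prs))) {
    add(combo_f2(basis, prs[1, q], prs[2, q]), "f2", prs[, q])
  }
  for (C in leaves) {
    rest <- setdiff(leaves, C)
    pr <- utils::combn(rest, 2)
    for (q in seq_len(ncol(pr))) {
      add(combo_f3(basis, C, pr[1, q], pr[2, q]), "f3", c(C, pr[, q]))
    }
  }
  if (length(leaves) >= 4) {
    quads <- utils::combn(leaves, 4)
    for (q in seq_len(ncol(quads))) {
      s <- quads[, q]
      add(combo_f4(basis, s[1], s[2], s[3], s[4]), "f4", s)
      add(combo_f4(basis, s[1], s[3], s[2], s[4]), "f4", s[c(1, 3, 2, 4)])
      add(combo_f4(basis, s[1], s[4], s[2], s[3]), "f4", s[c(1, 4, 2, 3)])
    }
  }
  C <- do.call(cbind, combos)
  obs <- combo_stats(basis, C)
  ef2 <- expected_fstats(graph)
  lab <- dplyr::bind_rows(labels)
  expv <- vapply(seq_len(nrow(lab)), function(i) {
    switch(lab$kind[i],
      f2 = ef2[lab$pop1[i], lab$pop2[i]],
      f3 = expected_f3(ef2, lab$pop1[i], lab$pop2[i], lab$pop3[i]),
      f4 = expected_f4(ef2, lab$pop1[i], lab$pop2[i], lab$pop3[i],
                       lab$pop4[i]))
  }, numeric(1))
  lab$observed <- obs$estimate
  lab$expected <- expv
  lab$se <- obs$se
  lab$z <- ifelse(obs$se > 0, (lab$observed - lab$expected) / lab$se,
                  NA_real_)
  lab
}

#' Fit an admixture graph to observed f-statistics
#'
#' Drift lengths and admixture weights minimize the inverse-variance
#' weighted sum of squared deviations between observed and expected basis
#' statistics `f3(base; i, j)` over all pairs of non-base leaves (the
#' weighting matrix is the diagonal of the jackknife covariance). The fit
#' uses bounded quasi-Newton optimization from one deterministic plus
#' `n_restarts - 1` seeded random starts. The quality score is
#' `worst_abs_z`, the largest |Z| between observed and expected values
#' over every f2, f3 and f4 of the fitted leaves.
#'
#' @param graph A `pf_graph` topology whose leaves are groups of `freqs`.
#' @param freqs A [group_freqs()] table (or a prebuilt basis via the
#'   `basis` argument).
#' @param base Base leaf for the f3 basis; defaults to the first leaf
#'   (conventionally the outgroup).
#' @param n_restarts Number of optimization starts.
#' @param seed Seed for the random starts.
#' @param basis Optionally a precomputed `fstat_basis` over the graph
#'   leaves (shared across candidate fits in the greedy search).
#' @param se_method Parameter standard errors: `"sandwich"` (fast
#'   Gauss-Newton curvature with the observed jackknife covariance; can
#'   understate uncertainty when parameters trade off along a flat
#'   profile) or `"jackknife"` (delete-one-block refits of the whole
#'   solve; slower, robust).
#' @return An object of class `pf_graphfit`: fitted `graph`, `objective`,
#'   `residuals` tibble, `worst_abs_z`, and approximate parameter
#'   standard errors (`par_se`, Gauss-Newton curvature).
#' @export
fit_graph <- function(graph, freqs = NULL, base = NULL, n_restarts = 10,
                      seed = 1L, basis = NULL,
                      se_method = c("sandwich", "jackknife")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(graph, "pf_graph"))
  if (is.null(basis)) {
    stopifnot(inherits(freqs, "pf_freqs"))
    basis <- fstat_basis(freqs, graph$leaves)
  }
  leaves <- graph$leaves
  if (!all(leaves %in% basis$groups)) {
    abort("every graph leaf needs data in the basis.")
  }
  base <- base %||% leaves[1]
  others <- setdiff(leaves, base)
  if (length(others) < 2) abort("need at least three leaves to fit a graph.")
  # f3(base; i, j) for all i <= j: the diagonal (i = j) equals f2(base, i),
  # completing the basis so leaf-specific drift is constrained too
  prs <- cbind(utils::combn(others, 2), rbind(others, others))
  C <- vapply(seq_len(ncol(prs)), function(q) {
    if (prs[1, q] == prs[2, q]) {
      combo_f2(basis, base, prs[1, q])
    } else {
      combo_f3(basis, base, prs[1, q], prs[2, q])
    }
  }, numeric(length(basis$pair_names)))
  obs <- combo_stats(basis, C)
  wt <- 1 / pmax(obs$se, 1e-9)^2
  i1 <- match(prs[1, ], leaves); i2 <- match(prs[2, ], leaves)
  ib <- match(base, leaves)

  ne <- nrow(graph$drift)
  na <- nrow(graph$admix)
  lower <- c(rep(0, ne), rep(0.001, na))
  upper <- c(rep(3, ne), rep(0.999, na))

  make_objective <- function(obs_est) {
    function(par) {
      gpar <- graph_par_set(graph, par)
      ef2 <- expected_fstats(gpar)
      expv <- (ef2[cbind(ib, i1)] + ef2[cbind(ib, i2)] -
                 ef2[cbind(i1, i2)]) / 2
      sum(wt * (obs_est - expv)^2)
    }
  }
  objective <- make_objective(obs$estimate)

  scale0 <- max(mean(abs(obs$estimate)), 1e-4)
  starts <- list(c(rep(scale0, ne), rep(0.5, na)))
  if (n_restarts > 1) {
    rs <- with_seed(seed, replicate(n_restarts - 1,
      c(runif(ne, 0, 3 * scale0), runif(na, 0.05, 0.95)),
      simplify = FALSE))
    starts <- c(starts, rs)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, objective, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("graph optimization failed from every start.")

  fitted <- graph_par_set(graph, best$par)
  res <- graph_residuals(fitted, basis, base)
  par_names <- c(
    paste0("edge:", graph$drift$parent, "->", graph$drift$child),
    if (na) paste0("alpha:", graph$admix$child))
  if (se_method == "jackknife") {
    # delete-one-block refits of the whole solve, from the optimum
    SC <- basis$S %*% C
    tot <- colSums(SC)
    n <- sum(basis$counts)
    g <- basis$n_blocks
    loo_par <- matrix(NA_real_, g, length(best$par))
    for (j in seq_len(g)) {
      est_j <- (tot - SC[j, ]) / (n - basis$counts[j])
      fj <- tryCatch(
        optim(best$par, make_objective(est_j), method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 200, factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(fj)) loo_par[j, ] <- fj$par
    }
    se <- vapply(seq_along(best$par), function(q) {
      ok <- !is.na(loo_par[, q])
      if (sum(ok) < 2) return(NA_real_)
      block_jackknife_loo_se(loo_par[ok, q], best$par[q], basis$counts[ok])
    }, numeric(1))
    par_se <- tibble::tibble(parameter = par_names, value = best$par,
                             se = se)
  } else {
    obs_cov <- combo_cov(basis, C)
    par_se <- gauss_newton_se(fitted, best$par, wt, obs_cov, ib, i1, i2)
  }

  worst <- suppressWarnings(max(abs(res$z), na.rm = TRUE))
  structure(
    list(graph = fitted, objective = best$value,
         residuals = res,
         worst_abs_z = if (is.finite(worst)) worst else NA_real_,
         par_se = par_se, base = base, n_snps = basis$n_snps,
         convergence = best$convergence),
    class = "pf_graphfit"
  )
}

# Sandwich (Gauss-Newton curvature + observed jackknife covariance)
# standard errors for the fitted parameters.
gauss_newton_se <- function(graph, par, wt, obs_cov, ib, i1, i2) {
  expfun <- function(p) {
    ef2 <- expected_fstats(graph_par_set(graph, p))
    (ef2[cbind(ib, i1)] + ef2[cbind(ib, i2)] - ef2[cbind(i1, i2)]) / 2
  }
  f0 <- expfun(par)
  J <- matrix(0, length(f0), length(par))
  for (q in seq_along(par)) {
    h <- max(1e-6, 1e-4 * abs(par[q]))
    pp <- par; pp[q] <- pp[q] + h
    pm <- par; pm[q] <- max(pm[q] - h, 0)
    J[, q] <- (expfun(pp) - expfun(pm)) / (pp[q] - pm[q])
  }
  H <- crossprod(J * sqrt(wt))
  Hinv <- tryCatch(solve(H), error = function(e) MASS_ginv(H))
  JW <- J * wt
  cv <- Hinv %*% t(JW) %*% obs_cov %*% JW %*% Hinv
  se <- sqrt(pmax(diag(cv), 0))
  tibble::tibble(parameter = c(
    paste0("edge:", graph$drift$parent, "->", graph$drift$child),
    if (nrow(graph$admix)) paste0("alpha:", graph$admix$child)),
    value = par, se = se)
}

# Moore-Penrose inverse via eigendecomposition (for singular curvature).
MASS_ginv <- function(H, tol = 1e-10) {
  ev <- eigen(H, symmetric = TRUE)
  pos <- ev$values > tol * max(ev$values)
  ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
}

#' @export
print.pf_graphfit <- function(x, ...) {
  cat(sprintf("<pf_graphfit> %d leaves, objective %.3g, worst |Z| = %.2f\n",
              length(x$graph$leaves), x$objective, x$worst_abs_z))
  invisible(x)
}

#' @export
tidy.pf_graphfit <- function(x, ...) x$residuals

#' @export
glance.pf_graphfit <- function(x, ...) {
  tibble::tibble(objective = x$objective, worst_abs_z = x$worst_abs_z,
                 n_leaves = length(x$graph$leaves),
                 n_admixtures = nrow(x$graph$admix), n_snps = x$n_snps)
}

#' Greedy addition of one population to a fitted graph
#'
#' Enumerates every way to attach `new_leaf` to the base graph: unadmixed
#' on each drift edge, and (unless disabled) as a two-way admixture
#' between every unordered pair of drift edges — `E + E (E - 1) / 2`
#' candidates for `E` edges. Each candidate is refitted and the one with
#' the lowest `worst_abs_z` wins; candidates within `tie_margin` of the
#' best score count as ties, broken toward fewer admixture events and then
#' lexicographically by attachment label. The margin matters because an
#' admixed attachment nests every unadmixed one, so it scores nominally
#' lower even when the extra admixture is spurious; a margin on the scale
#' of meaningful |Z| differences (default 0.5) acts as a parsimony guard.
#'
#' @param base_graph A `pf_graph` (or `pf_graphfit`) to extend.
#' @param new_leaf Group label to add.
#' @param freqs A [group_freqs()] table covering the new leaf too.
#' @param allow_admixture Permit admixed attachments.
#' @param n_restarts Optimization starts per candidate fit.
#' @param seed Seed for the candidate fits.
#' @param base Base leaf for the f3 basis.
#' @param tie_margin Score difference below which candidates tie.
#' @return A list with `fit` (best `pf_graphfit`) and `ledger` (tibble of
#'   every candidate with its score).
#' @export
greedy_add_population <- function(base_graph, new_leaf, freqs,
                                  allow_admixture = TRUE, n_restarts = 4,
                                  seed = 1L, base = NULL,
                                  tie_margin = 0.5) {
  if (inherits(base_graph, "pf_graphfit")) base_graph <- base_graph$graph
  stopifnot(inherits(base_graph, "pf_graph"))
  leaves <- c(base_graph$leaves, new_leaf)
  basis <- fstat_basis(freqs, leaves)
  E <- nrow(base_graph$drift)
  edge_lab <- paste(base_graph$drift$parent, base_graph$drift$child,
                    sep = "->")

  cands <- list()
  for (e in seq_len(E)) {
    cands[[length(cands) + 1]] <- list(
      type = "simple", label = edge_lab[e],
      graph = attach_leaf_simple(base_graph, new_leaf, e))
  }
  if (allow_admixture && E >= 2) {
    cmb <- utils::combn(E, 2)
    for (q in seq_len(ncol(cmb))) {
      e1 <- cmb[1, q]; e2 <- cmb[2, q]
      cands[[length(cands) + 1]] <- list(
        type = "admixed",
        label = paste(edge_lab[e1], edge_lab[e2], sep = " + "),
        graph = attach_leaf_admixed(base_graph, new_leaf, e1, e2))
    }
  }

  fits <- vector("list", length(cands))
  rows <- vector("list", length(cands))
  for (ci in seq_along(cands)) {
    fit <- tryCatch(
      fit_graph(cands[[ci]]$graph, base = base, n_restarts = n_restarts,
                seed = seed + ci, basis = basis),
      error = function(e) NULL)
    fits[[ci]] <- fit
    rows[[ci]] <- tibble::tibble(
      candidate = ci, type = cands[[ci]]$type, attachment = cands[[ci]]$label,
      worst_abs_z = if (is.null(fit)) NA_real_ else fit$worst_abs_z,
      objective = if (is.null(fit)) NA_real_ else fit$objective,
      n_admixtures = nrow(cands[[ci]]$graph$admix))
  }
  ledger <- dplyr::bind_rows(rows)
  ok <- which(!is.na(ledger$worst_abs_z))
  if (!length(ok)) abort("no candidate fit succeeded.")
  zmin <- min(ledger$worst_abs_z[ok])
  tied <- ok[ledger$worst_abs_z[ok] < zmin + tie_margin]
  tied <- tied[order(ledger$n_admixtures[tied], ledger$attachment[tied])]
  winner <- tied[1]
  list(fit = fits[[winner]], ledger = ledger, winner = winner)
}

#' Greedy graph growth over an ordered population list
#'
#' Starting from a fitted skeleton, repeatedly applies
#' [greedy_add_population()] in the given order, keeping the graph with
#' the lowest `worst_abs_z` at each step. Admixed attachments are refused
#' once `max_admixtures` admixture events are present.
#'
#' @param skeleton A `pf_graph` fitting the data.
#' @param ordered_pops Population labels to add, in order.
#' @param freqs A [group_freqs()] table covering all labels.
#' @param max_admixtures Global cap on admixture events (default 3).
#' @param n_restarts,seed,base Passed to the per-step fits.
#' @return A list with `fits` (one `pf_graphfit` per step, the last being
#'   the final model), `ledgers` (per-step candidate tables) and `final`.
#' @export
greedy_search <- function(skeleton, ordered_pops, freqs, max_admixtures = 3,
                          n_restarts = 4, seed = 1L, base = NULL,
                          tie_margin = 0.5) {
  stopifnot(inherits(skeleton, "pf_graph"))
  current <- skeleton
  fits <- list()
  ledgers <- list()
  if (length(ordered_pops) == 0) {
    fit <- fit_graph(skeleton, freqs, base = base, n_restarts = n_restarts,
                     seed = seed)
    return(list(fits = list(fit), ledgers = list(), final = fit))
  }
  for (s in seq_along(ordered_pops)) {
    allow <- nrow(current$admix) < max_admixtures
    step <- greedy_add_population(current, ordered_pops[s], freqs,
                                  allow_admixture = allow,
                                  n_restarts = n_restarts,
                                  seed = seed + 1000L * s, base = base,
                                  tie_margin = tie_margin)
    current <- step$fit$graph
    fits[[s]] <- step$fit
    ledgers[[s]] <- step$ledger
  }
  list(fits = fits, ledgers = ledgers, final = fits[[length(fits)]])
}
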