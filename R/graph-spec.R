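#' Construct an admixture graph
#'
#' A rooted directed acyclic graph in which drift edges carry f2-scale
#' branch lengths and admixture nodes combine two parent lineages with
#' mixing weight `alpha` (applied to `parentA`). Every non-root node has
#' either exactly one drift parent or exactly two admixture parents; leaves
#' are nodes with no children. The same object serves as simulation truth
#' for the drift simulator and as the target of graph fitting.
#'
#' @param drift Data frame with columns `parent`, `child`, `length`
#'   (`length >= 0`).
#' @param admix Data frame with columns `child`, `parentA`, `parentB`,
#'   `alpha` (in `[0, 1]`), or `NULL` for a tree.
#' @return An object of class `pf_graph`.
#' @export
pf_graph <- function(drift, admix = NULL) {
  drift <- tibble::as_tibble(drift)
  stopifnot(all(c("parent", "child", "length") %in% names(drift)))
  if (is.null(admix)) {
    admix <- tibble::tibble(child = character(), parentA = character(),
                            parentB = character(), alpha = numeric())
  }
  admix <- tibble::as_tibble(admix)
  if (any(drift$length < 0)) abort("drift edge lengths must be >= 0.")
  if (any(admix$alpha < 0 | admix$alpha > 1)) {
    abort("admixture weights must lie in [0, 1].")
  }

  children <- c(drift$child, admix$child)
  if (anyDuplicated(children)) {
    abort(sprintf("node '%s' has more than one parent specification.",
                  children[duplicated(children)][1]))
  }
  nodes <- unique(c(drift$parent, drift$child, admix$child,
                    admix$parentA, admix$parentB))
  roots <- setdiff(nodes, children)
  if (length(roots) != 1) {
    abort(sprintf("graph must have exactly one root (found: %s).",
                  paste(roots, collapse = ", ")))
  }

  g <- structure(list(drift = drift, admix = admix, root = roots,
                      nodes = nodes), class = "pf_graph")
  g$topo <- topo_sort(g) # errors on cycles
  parents <- unique(c(drift$parent, admix$parentA, admix$parentB))
  g$leaves <- setdiff(nodes, parents)
  g
}

# Topological order, root first. Errors on cycles.
topo_sort <- function(g) {
  edges <- rbind(
    data.frame(from = g$drift$parent, to = g$drift$child),
    data.frame(from = c(g$admix$parentA, g$admix$parentB),
               to = rep(g$admix$child, 2))
  )
  indeg <- table(factor(edges$to, levels = g$nodes))
  order <- character(0)
  avail <- g$nodes[indeg == 0]
  indeg <- as.vector(indeg)
  names(indeg) <- g$nodes
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    out <- edges$to[edges$from == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
    edges <- edges[edges$from != v, , drop = FALSE]
  }
  if (length(order) != length(g$nodes)) abort("graph contains a cycle.")
  order
}

#' @export
print.pf_graph <- function(x, ...) {
  cat(sprintf("<pf_graph> %d nodes, %d drift edges, %d admixture events\n",
              length(x$nodes), nrow(x$drift), nrow(x$admix)))
  cat("  leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

# Per-leaf probability that each drift edge lies on the ancestry lineage.
# Returns a leaves x edges matrix; exact for arbitrary nested admixture.
edge_lineage_weights <- function(g, leaves = g$leaves) {
  nodes <- g$topo
  nl <- length(leaves)
  C <- matrix(0, nl, length(nodes), dimnames = list(leaves, nodes))
  C[cbind(seq_len(nl), match(leaves, nodes))] <- 1
  W <- matrix(0, nl, nrow(g$drift),
              dimnames = list(leaves, paste(g$drift$parent, g$drift$child,
                                            sep = "->")))
  dchild <- match(g$drift$child, nodes)
  dparent <- match(g$drift$parent, nodes)
  achild <- match(g$admix$child, nodes)
  apa <- match(g$admix$parentA, nodes)
  apb <- match(g$admix$parentB, nodes)
  for (v in rev(seq_along(nodes))) { # children before parents
    ed <- which(dchild == v)
    if (length(ed) == 1L) {
      W[, ed] <- W[, ed] + C[, v]
      C[, dparent[ed]] <- C[, dparent[ed]] + C[, v]
    } else {
      ea <- which(achild == v)
      if (length(ea) == 1L) {
        a <- g$admix$alpha[ea]
        C[, apa[ea]] <- C[, apa[ea]] + a * C[, v]
        C[, apb[ea]] <- C[, apb[ea]] + (1 - a) * C[, v]
      }
    }
  }
  W
}

#' Expected f-statistics under an admixture graph
#'
#' Computes the expected f2 matrix over leaves by per-edge contributions:
#' the lineage of a leaf passes each drift edge with a probability given by
#' the product of admixture weights along its root paths, and
#' `f2(i, j) = sum_e (w_e(i) - w_e(j))^2 * length_e * het_scale`. This is
#' the path-counting form (the sum over root-path pairs of the drift on the
#' symmetric difference) collected per edge. Expected f3 and f4 follow from
#' the standard identities, see [expected_f3()] and [expected_f4()].
#'
#' @param graph A `pf_graph`.
#' @param het_scale Multiplier converting graph branch units to the scale
#'   of measured statistics. Branch lengths in the drift simulator are
#'   variances per unit of ancestral heterozygosity, so statistics measured
#'   on simulated frequencies carry a factor `E[p0 (1 - p0)]`; use
#'   [ancestral_het()] for it. For fitting, leave at 1 (the scale is
#'   absorbed into fitted lengths).
#' @return A symmetric leaves x leaves matrix of expected f2 values.
#' @export
expected_fstats <- function(graph, het_scale = 1) {
  W <- edge_lineage_weights(graph)
  A <- W %*% diag(sqrt(graph$drift$length), nrow(graph$drift))
  G <- tcrossprod(A)
  d <- diag(G)
  f2 <- (outer(d, d, "+") - 2 * G) * het_scale
  f2[f2 < 0] <- 0 # numerical guard
  dimnames(f2) <- list(graph$leaves, graph$leaves)
  f2
}

#' Expected f3 / f4 from an expected f2 matrix
#'
#' `f3(C; A, B) = (f2(C,A) + f2(C,B) - f2(A,B)) / 2` and
#' `f4(A, B; X, Y) = (f2(A,Y) + f2(B,X) - f2(A,X) - f2(B,Y)) / 2`.
#'
#' @param f2 Symmetric f2 matrix (e.g. from [expected_fstats()]).
#' @param C,A,B,X,Y Leaf labels.
#' @return A single expected value.
#' @export
expected_f3 <- function(f2, C, A, B) {
  (f2[C, A] + f2[C, B] - f2[A, B]) / 2
}

#' @rdname expected_f3
#' @export
expected_f4 <- function(f2, A, B, X, Y) {
  (f2[A, Y] + f2[B, X] - f2[A, X] - f2[B, Y]) / 2
}

#' Read / write admixture graphs as structured text
#'
#' One directive per line, tab- or space-separated: `root <node>`,
#' `edge <parent> <child> <length>`, `admix <child> <parentA> <parentB>
#' <alpha>`. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_graph` returns a `pf_graph`; `write_graph` its path,
#'   invisibly.
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  tok <- strsplit(lines, "[ \t]+")
  drift <- list()
  admix <- list()
  for (t in tok) {
    switch(t[1],
      root = NULL, # implied by topology; accepted for readability
      edge = {
        drift[[length(drift) + 1]] <-
          tibble::tibble(parent = t[2], child = t[3],
                         length = as.numeric(t[4]))
      },
      admix = {
        admix[[length(admix) + 1]] <-
          tibble::tibble(child = t[2], parentA = t[3], parentB = t[4],
                         alpha = as.numeric(t[5]))
      },
      abort(sprintf("unknown graph directive '%s' in %s", t[1], path))
    )
  }
  pf_graph(dplyr::bind_rows(drift),
           if (length(admix)) dplyr::bind_rows(admix) else NULL)
}

#' @rdname read_graph
#' @param graph A `pf_graph`.
#' @export
write_graph <- function(graph, path) {
  lines <- c(
    paste("root", graph$root),
    sprintf("edge %s %s %.10g", graph$drift$parent, graph$drift$child,
            graph$drift$length),
    if (nrow(graph$admix)) {
      sprintf("admix %s %s %s %.10g", graph$admix$child, graph$admix$parentA,
              graph$admix$parentB, graph$admix$alpha)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' The bundled eight-leaf example graph
#'
#' A fixture used throughout the package's tests and examples: an outgroup,
#' a northern lineage, an Amazonian lineage, two highland and two coastal
#' leaves, and one leaf admixed 50/50 between a highland-side and a
#' coastal-side ancestor. It mimics the shape of graphs used for Andean
#' ancient-DNA modelling at a scale where drift simulation is fast.
#'
#' @return A `pf_graph` with 8 leaves.
#' @export
example_graph <- function() {
  pf_graph(
    drift = tibble::tribble(
      ~parent, ~child, ~length,
      "R", "Outgroup", 0.08,
      "R", "anc1", 0.02,
      "anc1", "NorthAmerica", 0.04,
      "anc1", "anc2", 0.03,
      "anc2", "Amazon", 0.05,
      "anc2", "anc3", 0.02,
      "anc3", "ancH", 0.02,
      "anc3", "ancC", 0.02,
      "ancH", "HighlandsNorth", 0.02,
      "ancH", "hsAnc", 0.01,
      "hsAnc", "HighlandsSouth", 0.01,
      "ancC", "CoastNorth", 0.02,
      "ancC", "csAnc", 0.01,
      "csAnc", "CoastSouth", 0.01,
      "Madm", "Admixed", 0.01
    ),
    admix = tibble::tibble(child = "Madm", parentA = "hsAnc",
                           parentB = "csAnc", alpha = 0.5)
  )
}

# --- topology utilities used by the greedy search and its tests ----------

# Leaf bipartitions induced by drift edges whose descendant set is clean
# (every leaf either fully descends through the edge or not at all).
# Returns a character vector of canonical split strings.
graph_splits <- function(g, drop_leaves = character(0)) {
  W <- edge_lineage_weights(g)
  keep <- setdiff(rownames(W), drop_leaves)
  W <- W[keep, , drop = FALSE]
  splits <- character(0)
  for (e in seq_len(ncol(W))) {
    w <- W[, e]
    if (all(w < 1e-9 | w > 1 - 1e-9)) {
      side <- sort(names(w)[w > 0.5])
      if (length(side) >= 1 && length(side) <= length(keep) - 1) {
        other <- sort(setdiff(keep, side))
        canon <- if (paste(side, collapse = ",") <
                     paste(other, collapse = ",")) side else other
        splits <- c(splits, paste(canon, collapse = ","))
      }
    }
  }
  sort(unique(splits))
}

# Split a drift edge at a new internal node; returns the modified graph
# (lengths halved across the split so totals are preserved).
split_drift_edge <- function(g, edge_idx, new_node) {
  e <- g$drift[edge_idx, ]
  drift <- g$drift[-edge_idx, ]
  drift <- dplyr::bind_rows(
    drift,
    tibble::tibble(parent = e$parent, child = new_node,
                   length = e$length / 2),
    tibble::tibble(parent = new_node, child = e$child,
                   length = e$length / 2)
  )
  pf_graph(drift, g$admix)
}

# Attach `leaf` by a plain drift edge hanging off drift edge `edge_idx`.
attach_leaf_simple <- function(g, leaf, edge_idx, pendant = 0.01) {
  nn <- new_node_name(g)
  g2 <- split_drift_edge(g, edge_idx, nn)
  pf_graph(dplyr::bind_rows(g2$drift,
                            tibble::tibble(parent = nn, child = leaf,
                                           length = pendant)),
           g2$admix)
}

# Attach `leaf` as a two-way admixture between points on two drift edges.
attach_leaf_admixed <- function(g, leaf, edge_idx1, edge_idx2,
                                alpha = 0.5, pendant = 0.01) {
  stopifnot(edge_idx1 != edge_idx2)
  n1 <- new_node_name(g)
  # split the higher index first so the lower index stays valid
  ord <- sort(c(edge_idx1, edge_idx2), decreasing = TRUE)
  g2 <- split_drift_edge(g, ord[1], n1)
  n2 <- new_node_name(g2)
  g3 <- split_drift_edge(g2, ord[2], n2)
  mix <- paste0(leaf, "_mix")
  pf_graph(
    dplyr::bind_rows(g3$drift,
                     tibble::tibble(parent = mix, child = leaf,
                                    length = pendant)),
    dplyr::bind_rows(g3$admix,
                     tibble::tibble(child = mix, parentA = n1, parentB = n2,
                                    alpha = alpha))
  )
}

new_node_name <- function(g) {
  i <- 1L
  repeat {
    cand <- paste0("x", i)
    if (!cand %in% g$nodes) return(cand)
    i <- i + 1L
  }
}
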