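# ggplot2 display methods for result objects.

#' Plot an embedding (MDS or projection PCA)
#'
#' @param object A `pf_embedding`.
#' @param dims Two dimension numbers to display.
#' @param flip_dim1 Reverse the first displayed axis (a plotting-only
#'   convention sometimes used to align an embedding with geography).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_embedding <- function(object, dims = c(1, 2),
                                  flip_dim1 = FALSE, ...) {
  dn <- paste0("dim", dims)
  ve <- attr(object, "var_explained")
  lab <- function(i) {
    if (!is.null(ve) && length(ve) >= dims[i]) {
      sprintf("dimension %d (%.1f%%)", dims[i], 100 * ve[dims[i]])
    } else {
      sprintf("dimension %d", dims[i])
    }
  }
  df <- as.data.frame(object)
  if (flip_dim1) df[[dn[1]]] <- -df[[dn[1]]]
  colour <- if ("group" %in% names(df)) "group" else "label"
  aes <- if ("role" %in% names(df)) {
    ggplot2::aes(x = .data[[dn[1]]], y = .data[[dn[2]]],
                 colour = .data[[colour]], shape = .data$role)
  } else {
    ggplot2::aes(x = .data[[dn[1]]], y = .data[[dn[2]]],
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot an outgroup-f3 matrix as a heatmap
#'
#' @param object A `pf_f3matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_f3matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop2, y = .data$pop3,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("f3(%s; i, j)", object$outgroup)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a covariance decay curve with its fitted exponential
#'
#' @param object A `pf_decay`.
#' @param fit Optionally a `pf_date` from [fit_decay()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_decay <- function(object, fit = NULL, ...) {
  df <- object$curve[object$curve$n_pairs > 0, ]
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$bin_mid,
                                         y = .data$cov)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "genetic distance (cM)",
                  y = "weighted allele covariance") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    curve_df <- data.frame(
      d = df$bin_mid,
      y = fit$amplitude * exp(-fit$g * df$bin_mid) + fit$offset)
    gp <- gp + ggplot2::geom_line(
      data = curve_df, ggplot2::aes(x = 100 * .data$d, y = .data$y),
      colour = "firebrick")
  }
  gp
}

#' Export an admixture graph in DOT format
#'
#' Drift edges are labelled with their lengths (in thousandths), admixture
#' edges dashed with their weights; render with Graphviz.
#'
#' @param graph A `pf_graph`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dot <- function(graph, path) {
  lines <- c("digraph admixture_graph {",
             "  node [shape=plaintext];",
             sprintf("  \"%s\" -> \"%s\" [label=\"%d\"];",
                     graph$drift$parent, graph$drift$child,
                     round(1000 * graph$drift$length)))
  if (nrow(graph$admix)) {
    lines <- c(lines,
      sprintf("  \"%s\" -> \"%s\" [style=dashed,label=\"%d%%\"];",
              graph$admix$parentA, graph$admix$child,
              round(100 * graph$admix$alpha)),
      sprintf("  \"%s\" -> \"%s\" [style=dashed,label=\"%d%%\"];",
              graph$admix$parentB, graph$admix$child,
              round(100 * (1 - graph$admix$alpha))))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
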