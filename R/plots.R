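#' Plot a separation matrix as a heatmap
#'
#' @param object An `mdm_separation` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mdm_separation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$separation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "d(i, j)",
                  title = "Pairwise logBF separation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the 2-D classical MDS embedding of a separation matrix
#'
#' @param sep An `mdm_separation` matrix.
#' @param clusters Optional `mdm_clusters` assignment used to colour the
#'   points.
#' @return A ggplot.
#' @export
plot_mds <- function(sep, clusters = NULL) {
  fit <- classical_mds(sep, k = 2)
  df <- tibble::tibble(
    subject_id = rownames(sep),
    x = fit$points[, 1], y = fit$points[, 2]
  )
  if (!is.null(clusters)) {
    df <- dplyr::left_join(df, tibble::as_tibble(clusters),
                           by = "subject_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          colour = factor(.data$cluster)))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$subject_id),
                       vjust = -0.8, size = 2.7, show.legend = FALSE) +
    ggplot2::labs(
      x = "MDS 1", y = "MDS 2", colour = "subgroup",
      title = sprintf("Classical MDS (%.0f%% of separation captured)",
                      100 * fit$variance_explained)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a directed network on a circular layout
#'
#' @param object An [mdm_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mdm_network <- function(object, ...) {
  n <- length(object$parents)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble::tibble(node = seq_len(n), region = object$regions,
                          x = cos(ang), y = sin(ang))
  ed <- network_edges(object)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y))
  if (nrow(ed) > 0) {
    shrink <- 0.12
    seg <- tibble::tibble(
      x = nodes$x[ed$from], y = nodes$y[ed$from],
      xend = nodes$x[ed$to], yend = nodes$y[ed$to]
    )
    seg <- dplyr::mutate(
      seg,
      dx = .data$xend - .data$x, dy = .data$yend - .data$y,
      len = sqrt(.data$dx^2 + .data$dy^2),
      xend = .data$xend - shrink * .data$dx / .data$len,
      yend = .data$yend - shrink * .data$dy / .data$len
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
      colour = "grey40"
    )
  }
  p + ggplot2::geom_point(size = 6, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$region), size = 2.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0(
      if (object$acyclic) "DAG" else "Directed graph",
      " (", nrow(ed), " edges)"))
}

#' Plot a lambda-selection path
#'
#' @param object The result of [select_lambda()].
#' @param ... Unused.
#' @return A ggplot of the criterion and the per-level edge counts
#'   against lambda (log scale).
#' @export
autoplot_lambda_path <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$path,
    c("mean_individual_edges", "mean_subgroup_edges", "group_edges"),
    names_to = "level", values_to = "edges"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$edges,
                                   colour = .data$level)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "edges",
                  title = "Network density across the penalty sweep") +
    ggplot2::theme_minimal()
}

#' Export a network in Graphviz DOT format
#'
#' @param net An [mdm_network()].
#' @param path Optional file to write; otherwise the DOT string is
#'   returned.
#' @return The DOT source, invisibly when written to `path`.
#' @export
network_to_dot <- function(net, path = NULL) {
  ed <- network_edges(net)
  lines <- c(
    "digraph mdm {",
    sprintf("  \"%s\";", net$regions),
    sprintf("  \"%s\" -> \"%s\";",
            net$regions[ed$from], net$regions[ed$to]),
    "}"
  )
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
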