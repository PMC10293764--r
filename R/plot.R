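# ggplot2 views of spectra and annotations.

#' Plot a profile or centroided spectrum
#'
#' Profile points are drawn as vertical stems; detected peaks, when given,
#' are overlaid at their centroids.
#'
#' @param points Data frame with `mz` and `intensity`.
#' @param peaks Optional [pick_peaks()] tibble to overlay.
#' @return A ggplot object.
#' @examples
#' pts <- simulate_spectrum(simulation_spec("C6NH6+", seed = 1))
#' plot_spectrum(pts)
#' @export
plot_spectrum <- function(points, peaks = NULL) {
  .check_points(points)
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$mz, y = 0, yend = .data$intensity),
      linewidth = 0.3, colour = "grey40"
    ) +
    ggplot2::labs(x = "m/z (Da)", y = "Intensity (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$measured_mz, y = .data$total_intensity),
      colour = "firebrick", shape = 17
    )
  }
  p
}

#' Plot an annotated MS2 spectrum
#'
#' Stem plot of relative intensity against m/z with formula labels on
#' annotated peaks; unannotated peaks are grey.
#'
#' @param object A `frag_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.frag_annotation <- function(object, ...) {
  res <- object$results
  res$height <- dplyr::coalesce(res$relative_intensity_pct, 1)
  res$annotated <- !is.na(res$formula)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$measured_mz)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$measured_mz, y = 0, yend = .data$height,
                   colour = .data$annotated),
      linewidth = 0.6, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      data = res[res$annotated, ],
      ggplot2::aes(y = .data$height, label = .data$formula),
      angle = 90, hjust = -0.05, size = 2.8
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.35))) +
    ggplot2::labs(
      x = "m/z (Da)", y = "Relative intensity (%)",
      title = sprintf("Precursor %s at m/z %.4f",
                      object$precursor$formula %||% "?", object$target_mz)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fragments network
#'
#' Nodes are placed along the m/z (or index) axis; consistency edges are
#' drawn as arcs, each labelled with its neutral loss.
#'
#' @param object A `fragments_network` from [build_network()] or
#'   [select_best()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.fragments_network <- function(object, ...) {
  nodes <- object$nodes
  nodes$x <- if ("measured_mz" %in% names(nodes) &&
                 !all(is.na(nodes$measured_mz))) {
    nodes$measured_mz
  } else if ("predicted_mz" %in% names(nodes)) {
    nodes$predicted_mz
  } else {
    seq_len(nrow(nodes))
  }
  edges <- object$edges
  edges$x <- nodes$x[match(edges$parent, nodes$peak)]
  edges$xend <- nodes$x[match(edges$child, nodes$peak)]
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = 0))
  if (nrow(edges) > 0L) {
    p <- p + ggplot2::geom_curve(
      data = edges,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      curvature = -0.25, colour = "steelblue", alpha = 0.6
    )
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$formula),
                       angle = 45, hjust = -0.1, vjust = -0.5, size = 2.8) +
    ggplot2::scale_y_continuous(limits = c(-0.2, 1), breaks = NULL) +
    ggplot2::labs(x = "m/z (Da)", y = NULL,
                  title = sprintf("Fragments network, grade %d", object$grade)) +
    ggplot2::theme_minimal()
}
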