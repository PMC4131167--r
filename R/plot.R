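#' Plot a fitted network pair
#'
#' Draws the inferred networks with edges coloured by condition
#' membership: common edges in grey, condition-specific (differential)
#' edges in the condition's colour. Uses an igraph layout when igraph is
#' installed, otherwise a circular layout.
#'
#' @param object A `kddn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kddn_fit
#' @export
autoplot.kddn_fit <- function(object, ...) {
  edges <- object$edges
  genes <- object$genes
  if (requireNamespace("igraph", quietly = TRUE) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("node_a", "node_b")], directed = FALSE,
      vertices = data.frame(name = genes))
    xy <- igraph::layout_with_fr(g)
  } else {
    ang <- seq(0, 2 * pi, length.out = length(genes) + 1)[seq_along(genes)]
    xy <- cbind(cos(ang), sin(ang))
  }
  nodes <- tibble::tibble(gene = genes, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::left_join(edges, nodes, by = c("node_a" = "gene")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    dplyr::left_join(nodes, by = c("node_b" = "gene")) |>
    dplyr::rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$condition),
      linewidth = 0.5) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 1.5, colour = "grey30") +
    ggplot2::scale_colour_manual(
      values = c(both = "grey60", cond1 = "#D55E00", cond2 = "#009E73"),
      name = "present in") +
    ggplot2::theme_void()
}

#' Plot a theta calibration curve
#'
#' Mean relative graph edit distance to the data-only network as a
#' function of the knowledge weight, with the degradation budget and the
#' selected value marked.
#'
#' @param object A `kddn_theta_calibration` from [select_theta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kddn_theta_calibration
#' @export
autoplot.kddn_theta_calibration <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$theta,
                                    y = .data$mean_distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$feasible)) +
    ggplot2::geom_hline(yintercept = object$delta, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$theta_hat, linetype = 3) +
    ggplot2::labs(x = "knowledge weight θ",
                  y = "mean relative edit distance to data-only network") +
    ggplot2::theme_minimal()
}

#' Plot a false-positive-rate sweep
#'
#' Mean precision and recall per method against the knowledge
#' false-positive rate, one panel per scope and metric.
#'
#' @param sweep The tibble returned by [run_fp_sweep()].
#' @return A ggplot object.
#' @export
plot_fp_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$fp_rate, y = .data$mean,
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd), width = 0.02) +
    ggplot2::facet_grid(.data$metric ~ .data$scope) +
    ggplot2::labs(x = "false positive rate in prior knowledge",
                  y = NULL) +
    ggplot2::theme_minimal()
}
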