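#' Plot an isolation-by-distance regression
#'
#' Scatter of linearized pairwise F_ST against distance with the fitted OLS
#' line and the fit statistics in the subtitle.
#'
#' @param object A `wasp_ibd` from [ibd_regression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wasp_ibd <- function(object, ...) {
  df <- object$pairs[is.finite(object$pairs$fst_linearized), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$km, y = .data$fst_linearized)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope_b,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(
      x = "geographic distance (km)",
      y = expression(F[ST] / (1 - F[ST])),
      subtitle = sprintf("b = %.3g /km, R² = %.2f, p = %.3g",
                         object$slope_b, object$r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the first two MDS axes
#'
#' @param object A `wasp_mds` from [classical_mds()].
#' @param colour Optional vector (same order as samples) used to colour
#'   points, e.g. region labels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wasp_mds <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$C1, y = .data$C2))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(x = "C1", y = "C2") + ggplot2::theme_minimal()
}

#' Plot a minimum-spanning haplotype network
#'
#' Nodes (area proportional to haplotype count) placed by a seeded
#' Fruchterman-Reingold layout of the spanning tree; alternative
#' equal-weight links drawn dashed.
#'
#' @param object A `haplotype_network` from [build_haplotype_network()].
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplotype_network <- function(object, seed = 1L, ...) {
  nodes <- object$nodes
  edges <- object$edges
  gr <- igraph::graph_from_data_frame(
    edges[!edges$is_alternative, c("from", "to")],
    directed = FALSE, vertices = nodes$haplotype)
  set.seed(seed)
  xy <- igraph::layout_with_fr(gr)
  lay <- tibble::tibble(haplotype = nodes$haplotype,
                        x = xy[, 1], y = xy[, 2], count = nodes$count)
  seg <- dplyr::left_join(edges, lay, by = c(from = "haplotype")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c(to = "haplotype"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linetype = .data$is_alternative),
      colour = "grey50") +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$count),
      colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(
      data = seg[seg$steps > 1, ],
      ggplot2::aes(x = (.data$x0 + .data$x) / 2,
                   y = (.data$y0 + .data$y) / 2, label = .data$steps),
      size = 3) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "sequences")
}
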