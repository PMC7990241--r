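# ggplot2 views of the result objects: plot-ready data stays accessible via
# tidy(); these are convenience renderers.

#' PCA score (or loading) plot
#'
#' @param object A `metabo_pca`.
#' @param components Two component indices (default `c(1, 2)`).
#' @param groups Optional per-sample group labels for colouring.
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metabo_pca <- function(object, components = c(1, 2), groups = NULL,
                                matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  pcs <- paste0("PC", components)
  evf <- object$explained_variance_fraction[components]
  labs <- sprintf("%s (%.1f%%)", pcs, 100 * evf)
  df <- if (matrix == "scores") object$scores else object$loadings
  if (!all(pcs %in% names(df))) abort_mp("component not present in result")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[pcs[1]]],
                                        y = .data[[pcs[2]]]))
  if (matrix == "scores" && !is.null(groups)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(groups)),
                                 size = 2) +
      ggplot2::labs(colour = "group")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = labs[1], y = labs[2]) + ggplot2::theme_minimal()
}

#' Volcano plot of a per-metabolite statistics table
#'
#' Log2 fold change against -log10 p, with the selection rectangle implied by
#' the thresholds; selected metabolites are highlighted.
#'
#' @param stats A `metabo_stats` tibble from [metabolite_stats()] (or any
#'   tibble with `log2_fc`, `p_value`, `selected`).
#' @param min_abs_log2_fc,max_p Threshold guide lines (defaults read from the
#'   attributes when present).
#' @return A ggplot.
#' @export
plot_volcano <- function(stats, min_abs_log2_fc = NULL, max_p = NULL) {
  th <- attr(stats, "thresholds")
  min_abs_log2_fc <- min_abs_log2_fc %||%
    (if (!is.null(th)) th[["min_abs_log2_fc"]] else 1)
  max_p <- max_p %||% (if (!is.null(th)) th[["max_p"]] else 0.05)
  df <- dplyr::filter(stats, !is.na(.data$log2_fc), !is.na(.data$p_value))
  sel <- if ("selected" %in% names(df)) df$selected else FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = sel), alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "orange"),
                                 name = "selected") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_log2_fc,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(max_p), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Correlation network plot
#'
#' Force-directed layout (Fruchterman-Reingold via igraph); edge colour gives
#' the correlation sign (negative red, positive grey), width its magnitude.
#'
#' @param object A `metabo_network`.
#' @param seed Layout seed for reproducibility.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metabo_network <- function(object, seed = 1L, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")],
    directed = FALSE,
    vertices = object$nodes$metabolite
  )
  xy <- with_seed_mp(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "metabolite", x0 = "x", y0 = "y"),
                     by = c(from = "metabolite")) |>
    dplyr::left_join(dplyr::select(nodes, "metabolite", x1 = "x", y1 = "y"),
                     by = c(to = "metabolite"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign,
                   linewidth = .data$weight), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(positive = "grey40",
                                            negative = "red")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::theme_void()
}
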