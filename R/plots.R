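#' @rdname diff_expression
#' @method autoplot cerna_de
#' @export
autoplot.cerna_de <- function(object, ...) {
  d <- object$results |>
    mutate(neglog10p = -log10(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$neglog10p,
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$thresholds$lfc,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$p),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2471a3",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (knockout / control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_samples
#' @param object A `cerna_qc` object.
#' @method autoplot cerna_qc
#' @export
autoplot.cerna_qc <- function(object, ...) {
  d <- tidy(object)
  ve <- object$pca$var_explained
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[["PC1"]]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[["PC2"]]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sample correlation heatmap
#'
#' @param qc A [qc_samples()] result.
#' @return A ggplot.
#' @export
plot_sample_correlation <- function(qc) {
  r <- qc$correlation
  d <- as_tibble(r, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname build_network
#' @param object A `cerna_network` object.
#' @method autoplot cerna_network
#' @export
autoplot.cerna_network <- function(object, ...) {
  g <- object$graph
  set.seed(1) # layout only; analysis results never depend on it
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "name", xa = "x", ya = "y"),
              by = c(from = "name")) |>
    left_join(select(nodes, "name", xb = "x", yb = "y"),
              by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       colour = .data$type),
                          linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type),
                        size = 2) +
    ggplot2::labs(colour = "edge", shape = "node") +
    ggplot2::theme_void()
}

#' Top enriched terms
#'
#' Bar chart of the most significant terms per category.
#'
#' @param results Output of [hypergeom_enrich()] or [screen_terms()].
#' @param n Terms per category (default 10).
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, n = 10) {
  d <- results |>
    group_by(.data$category) |>
    arrange(.data$p_adjusted, .by_group = TRUE) |>
    slice_head(n = n) |>
    ungroup() |>
    mutate(term_id = factor(.data$term_id, levels = rev(unique(.data$term_id))))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_adjusted),
                                  y = .data$term_id,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
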