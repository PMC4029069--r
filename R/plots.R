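# ggplot2 visualisations for the main result types.

#' Volcano plot of a pairwise comparison
#'
#' @param object An `ndeg_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ndeg_comparison
#' @export
autoplot.ndeg_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-thr[["lfc"]], thr[["lfc"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      title = paste("Comparison", attr(object, "comparison")),
      x = "log2 fold change (sensitive/tolerant)",
      y = "-log10 FDR", colour = "DEG"
    ) +
    ggplot2::theme_minimal()
}

#' Membership histogram of a consensus result
#'
#' Bar chart of the number of genes differentially expressed in at least
#' `n` of the cross-group comparisons, for `n = 1` up to the number of
#' comparisons.
#'
#' @param object An `ndeg_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ndeg_consensus
#' @export
autoplot.ndeg_consensus <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = factor(.data$n), y = .data$genes_at_least_n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$n_min - 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "n (comparisons in which a gene is a DEG)",
      y = "genes with membership >= n"
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' @param object An `ndeg_enrichment`.
#' @param top Number of top terms (by p-value) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ndeg_enrichment
#' @export
autoplot.ndeg_enrichment <- function(object, top = 20, ...) {
  df <- head(tibble::as_tibble(object), top)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$term_name,
                                   size = .data$m, colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "DEGs in term",
                  colour = "enriched") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ndeg_comparison
#' @param x An `ndeg_comparison`.
#' @export
plot_volcano <- function(x, ...) autoplot.ndeg_comparison(x, ...)

#' @rdname autoplot.ndeg_consensus
#' @param x An `ndeg_consensus`.
#' @export
plot_membership_histogram <- function(x, ...) autoplot.ndeg_consensus(x, ...)

#' @rdname autoplot.ndeg_enrichment
#' @param x An `ndeg_enrichment`.
#' @export
plot_enrichment <- function(x, top = 20, ...) autoplot.ndeg_enrichment(x, top = top, ...)
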