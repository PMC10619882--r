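#' Dot plot of per-cluster marker expression
#'
#' Dot size encodes the fraction of expressing cells, colour the mean
#' log-normalized expression — the standard summary for marker panels.
#'
#' @param object a `dotplot_stats` tibble from [marker_summary()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dotplot_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gene, y = .data$cluster)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pct_expressing,
                                     colour = .data$mean_expression)) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1),
                             name = "fraction expressing") +
    ggplot2::scale_colour_viridis_c(name = "mean expression") +
    ggplot2::labs(x = NULL, y = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of bulk-type vs cluster correlations
#'
#' @param object a `correlation_assignment` from [match_bulk_to_clusters()].
#' @param ... unused.
#' @return A ggplot object; the best match per type is outlined.
#' @export
autoplot.correlation_assignment <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cluster, y = .data$type)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r)) +
    ggplot2::geom_tile(data = dplyr::filter(long, .data$is_best_match),
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = "cluster", y = "bulk type") +
    ggplot2::theme_minimal()
}

#' Heat strip of grouped enrichment terms
#'
#' Terms in tree order, shaded by `-log10(FDR)`.
#'
#' @param object a `term_grouping` from [group_terms()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.term_grouping <- function(object, ...) {
  tab <- dplyr::mutate(object$table,
                       name = factor(.data$name, levels = rev(.data$name)))
  ggplot2::ggplot(tab, ggplot2::aes(x = 1, y = .data$name,
                                    fill = .data$neg_log10_fdr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10(FDR)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Per-region HCR positivity bars
#'
#' @param object an `hcr_positivity` from [score_hcr_positivity()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hcr_positivity <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$region,
                               y = .data$positive_fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                name = "positive fraction") +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
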