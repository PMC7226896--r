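#' Hockey-stick plot of ranked enhancers
#'
#' The classic SE rank curve: regions ordered by ascending signal, with
#' the tangent cutoff marked and super enhancers highlighted.
#'
#' @param ranked Output of [call_superenhancers()].
#' @return A ggplot object.
#' @export
plot_rank_curve <- function(ranked) {
  check_columns(ranked, c("signal", "se_flag"), "ranked enhancers")
  df <- ranked %>%
    arrange(.data$signal) %>%
    mutate(asc_rank = row_number())
  cutoff <- attr(ranked, "cutoff_signal")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$asc_rank,
                                        y = .data$signal,
                                        color = .data$se_flag)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      name = "super enhancer"
    ) +
    ggplot2::labs(x = "enhancer rank (ascending signal)",
                  y = "signal (summed over constituents)") +
    ggplot2::theme_minimal()
  if (is.finite(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff,
                                 linetype = "dashed", color = "grey30")
  }
  p
}

#' @rdname plot_rank_curve
#' @param object A `miswire_ranked` table.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.miswire_ranked <- function(object, ...) plot_rank_curve(object)

#' Box/violin view of per-group imbalance scores
#'
#' Mirrors the cohort view of the exonic-imbalance analysis: one box per
#' sample group of the per-sample Z* for a chosen gene.
#'
#' @param scores An [imbalance_table()] result carrying a `group` column.
#' @param gene Gene to display (default: all, faceted).
#' @return A ggplot object.
#' @export
plot_imbalance <- function(scores, gene = NULL) {
  check_columns(scores, c("gene_id", "group", "z_star"),
                "imbalance scores")
  if (!is.null(gene)) {
    scores <- scores %>% filter(.data$gene_id %in% gene)
  }
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$group,
                                       y = .data$z_star)) +
    ggplot2::geom_violin(fill = "grey85", color = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.25, outlier.size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "exonic imbalance Z*") +
    ggplot2::theme_minimal()
}

#' @rdname plot_imbalance
#' @param object An `imbalance_scores` table.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.imbalance_scores <- function(object, ...) plot_imbalance(object)

#' Dropout by regulatory-element class
#'
#' Box plot of per-element log2 fold changes, ordered by median — the
#' screen's class-level negative-selection summary.
#'
#' @param scores Per-element scores, e.g. [terminal_scores()].
#' @return A ggplot object.
#' @export
plot_element_lfc <- function(scores) {
  check_columns(scores, c("class", "element_lfc"), "element scores")
  scores <- scores %>%
    mutate(class = stats::reorder(.data$class, .data$element_lfc, median))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$class,
                                       y = .data$element_lfc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "element log2 fold change vs reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
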