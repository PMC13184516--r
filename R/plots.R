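#' Per-drug prediction scatter
#'
#' Predicted vs true responses for every matched pair (gray background
#' points), with quadratic trend lines for the `k_highlight` drugs with
#' the highest per-drug SCC (green) and the `k_highlight` with the lowest
#' (red) — the at-a-glance picture of whether strong overall correlation
#' hides drugs the model cannot rank.
#'
#' The exact table behind the plot (including the highlighted drug ids
#' and their SCCs) is attached as `attr(p, "plot_data")`; tests compare
#' that, never pixels.
#'
#' @param truth a [triplet_dataset()].
#' @param pred a [prediction_table()].
#' @param k_highlight drugs highlighted on each side (default 2).
#' @param min_pairs per-drug scoring floor.
#' @return a ggplot object.
#' @export
plot_per_drug_scatter <- function(truth, pred, k_highlight = 2, min_pairs = 3) {
  per_drug <- per_drug_metrics(truth, pred, min_pairs)
  scorable <- per_drug[!is.na(per_drug$scc), , drop = FALSE]
  if (nrow(scorable) == 0) stop_drp("no scorable drug to plot")
  ord <- scorable[order(scorable$scc, decreasing = TRUE), ]
  k <- min(k_highlight, ceiling(nrow(ord) / 2))
  best <- head(ord$drug_id, k)
  worst <- utils::tail(ord$drug_id, k)
  worst <- setdiff(worst, best)

  joined <- join_truth_pred(truth, pred)$joined
  joined$highlight <- ifelse(joined$drug_id %in% best, "best",
                             ifelse(joined$drug_id %in% worst, "worst", "other"))
  rtype <- response_type(truth)
  p <- ggplot2::ggplot(joined,
                       ggplot2::aes(x = .data$response, y = .data$predicted)) +
    ggplot2::geom_point(data = joined[joined$highlight == "other", ],
                        color = "grey70", alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(data = joined[joined$highlight != "other", ],
                        ggplot2::aes(color = .data$highlight), size = 1.2) +
    ggplot2::geom_smooth(
      data = joined[joined$highlight != "other", ],
      ggplot2::aes(color = .data$highlight, group = .data$drug_id),
      method = "lm", formula = y ~ poly(x, 2), se = FALSE, linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(best = "forestgreen", worst = "firebrick"),
                                name = "per-drug SCC") +
    ggplot2::labs(x = sprintf("true response (%s)", rtype),
                  y = sprintf("predicted response (%s)", rtype)) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- list(
    points = joined,
    highlighted = per_drug[per_drug$drug_id %in% c(best, worst), ],
    best = best, worst = worst)
  p
}

#' Per-drug SCC waterfall plot
#'
#' Drugs sorted descending by the chosen metric, one bar each, a
#' threshold line, and an annotation giving the percentage of scorable
#' drugs strictly above the threshold. Unscorable drugs are reported in
#' the caption. The plotted table (sorted values plus the
#' [fraction_above()] summary) is attached as `attr(p, "plot_data")`.
#'
#' @param per_drug_table output of [per_drug_metrics()].
#' @param metric column to plot (default `"scc"`).
#' @param threshold threshold line (default 0.5).
#' @return a ggplot object.
#' @export
plot_waterfall <- function(per_drug_table, metric = "scc", threshold = 0.5) {
  vals <- per_drug_table[[metric]]
  if (is.null(vals)) stop_drp("no metric column '%s'", metric)
  scorable <- per_drug_table[!is.na(vals), , drop = FALSE]
  if (nrow(scorable) == 0) stop_drp("no scorable drug to plot")
  scorable <- scorable[order(scorable[[metric]], decreasing = TRUE), ]
  scorable$rank <- seq_len(nrow(scorable))
  fa <- fraction_above(per_drug_table, metric, threshold)
  annotation <- sprintf("%.0f%% of drugs with %s > %.2f",
                        100 * fa$fraction, toupper(metric), threshold)
  caption <- if (fa$n_unscorable > 0) {
    sprintf("%d drug(s) unscorable (too few pairs or constant values)",
            fa$n_unscorable)
  } else NULL
  p <- ggplot2::ggplot(scorable,
                       ggplot2::aes(x = .data$rank, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue", width = 0.9) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::annotate("text", x = nrow(scorable), y = max(scorable[[metric]]),
                      hjust = 1, vjust = 1, label = annotation) +
    ggplot2::labs(x = "drug rank", y = toupper(metric), caption = caption) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- list(
    bars = scorable[c("drug_id", "n_pairs", metric, "rank")],
    threshold = threshold, fraction_above = fa$fraction,
    annotation = annotation, n_unscorable = fa$n_unscorable)
  p
}

#' Cross-dataset Spearman heatmap
#'
#' Red-to-green diverging heatmap of a [cross_dataset_matrix()], each cell
#' annotated with its Spearman value and matched-pair count; undefined
#' cells (overlap below the matrix's `min_overlap`) are rendered neutral
#' gray with an "n < min" annotation. The annotation table is attached as
#' `attr(p, "plot_data")`.
#'
#' @param matrix a `cross_dataset_matrix`.
#' @return a ggplot object.
#' @export
plot_cross_dataset_heatmap <- function(matrix) {
  nm <- matrix$dataset_names
  grid <- expand.grid(row = nm, col = nm, stringsAsFactors = FALSE)
  grid$scc <- mapply(function(r, c) matrix$scc[r, c], grid$row, grid$col)
  grid$n <- mapply(function(r, c) matrix$n_overlap[r, c], grid$row, grid$col)
  grid$label <- ifelse(is.na(grid$scc),
                       sprintf("n < %d\n(n=%d)", matrix$min_overlap, grid$n),
                       sprintf("%.2f\nn=%d", grid$scc, grid$n))
  grid$row <- factor(grid$row, levels = rev(nm))
  grid$col <- factor(grid$col, levels = nm)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$scc)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "lightyellow",
                                  high = "forestgreen", midpoint = 0.5,
                                  limits = c(-1, 1), na.value = "grey85",
                                  name = "Spearman") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- grid
  p
}
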