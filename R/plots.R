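#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sorted MSL' curve of a cluster set
#'
#' Plots the size-normalised mean squared loss of every cluster in ascending
#' order, the diagnostic used to place the split threshold at the point of
#' steepest ascent.
#'
#' @param clusters A `cluster_set` with diagnostics (from
#'   [refine_clusters()]), or the diagnostics tibble itself.
#' @param threshold Reference line; default 0.65.
#' @return A ggplot object.
#' @export
plot_msl_curve <- function(clusters, threshold = 0.65) {
  diag <- if (inherits(clusters, "cluster_set")) clusters$diagnostics else clusters
  if (is.null(diag)) stop("no loss diagnostics; run refine_clusters() first", call. = FALSE)
  df <- diag[!is.na(diag$msl_prime), ]
  df <- df[order(df$msl_prime), ]
  df$ix <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ix, y = .data$msl_prime)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "cluster (sorted)", y = "MSL'",
                  title = "Size-normalised projection loss per cluster") +
    ggplot2::theme_minimal()
}

#' Accuracy distribution of a combination ranking
#'
#' @param object A `combo_ranking`.
#' @param ... Unused.
#' @return A ggplot object: total accuracy against rank, one panel per
#'   combination size.
#' @export
autoplot.combo_ranking <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rank, y = .data$total_accuracy)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~k, scales = "free_x", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "rank", y = "total accuracy (5-fold CV)",
                  title = "Ranked k-combinations") +
    ggplot2::theme_minimal()
}

#' Search quality by criterion
#'
#' @param object A [compare_criteria()] table.
#' @param ... Unused.
#' @return A ggplot object: average true rank per criterion, faceted by k
#'   and top-list length.
#' @export
plot_benchmark <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$criterion, y = .data$avg_rank)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(k ~ n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "selection criterion", y = "average true rank",
                  title = "Search quality against the exhaustive oracle") +
    ggplot2::theme_minimal()
}
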