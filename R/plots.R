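## ggplot2 helpers for the standard displays: average binding profiles,
## ranked signal heatmaps, genomic-distribution bars and fold-change boxes.

#' Plot an average binding profile
#'
#' @param mat A `signal_matrix` from [build_matrix()], or a profile tibble
#'   from [average_profile()].
#' @return A ggplot.
#' @export
plot_average_profile <- function(mat) {
  prof <- if (inherits(mat, "signal_matrix")) average_profile(mat) else mat
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$offset,
                                     y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from region center (bp)",
                  y = "mean normalized read count") +
    ggplot2::theme_classic()
}

#' Heatmap of a signal matrix
#'
#' Rows are regions ranked by descending center intensity (see
#' [rank_regions()]), columns are bins around the region center.
#'
#' @param object A `signal_matrix`.
#' @param rank_window Center-window width used for row ranking.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, rank_window = 400, ...) {
  ord <- rank_regions(object, window = rank_window)
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object)),
    offset = as.numeric(colnames(object))
  )
  df$signal <- as.vector(t(unclass(object)[ord, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$row,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3") +
    ggplot2::labs(x = "distance from region center (bp)",
                  y = "regions (ranked by center intensity)",
                  fill = "signal") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked bar chart of genomic distributions
#'
#' @param dist Tibble from [genomic_distribution()], optionally with a
#'   `set` column distinguishing several peak sets.
#' @return A ggplot.
#' @export
plot_genomic_distribution <- function(dist) {
  if (!"set" %in% names(dist)) dist$set <- "peaks"
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$set, y = .data$fraction,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of binding sites",
                  fill = "state") +
    ggplot2::theme_classic()
}

#' Box plot of per-region log2 fold changes
#'
#' @param fc Tibble with columns `group` and `log2_ratio` (one row per
#'   region), e.g. assembled from [log2_fold_changes()] across factors.
#' @return A ggplot.
#' @export
plot_fold_changes <- function(fc) {
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$group, y = .data$log2_ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "log2 fold change") +
    ggplot2::theme_classic()
}
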