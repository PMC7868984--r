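#' Plot SV size distributions per sample
#'
#' Box plots of SV sizes (log10 scale) per sample, optionally coloured by
#' group.
#'
#' @param calls SV call tibble.
#' @param groups Optional tibble `sample_id`, `group`.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(calls, groups = NULL) {
  df <- calls
  if (!is.null(groups)) {
    df <- dplyr::left_join(df, groups, by = "sample_id")
  } else {
    df$group <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$svlen, fill = .data$group
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "SV size (bp)", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-window SV counts along chromosomes
#'
#' @param window_counts Output of [sv_window_counts()].
#' @return A ggplot object (one facet per chromosome, colour per SV type).
#' @export
plot_window_counts <- function(window_counts) {
  ggplot2::ggplot(window_counts, ggplot2::aes(
    x = (.data$window_start + .data$window_end) / 2e6,
    y = .data$n, colour = .data$svtype
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "SV per window", colour = "type") +
    ggplot2::theme_minimal()
}

#' Plot block-median depth with called segments
#'
#' @param blocks Output of [block_medians()].
#' @param segments Optional segment tibble from [call_duplications()].
#' @return A ggplot object.
#' @export
plot_depth <- function(blocks, segments = NULL) {
  p <- ggplot2::ggplot(blocks, ggplot2::aes(
    x = .data$start / 1e6, y = .data$median_depth
  )) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "median block depth") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(
        xmin = .data$start / 1e6, xmax = .data$end / 1e6,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "red", alpha = 0.2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.subgenome_rates <- function(object, ...) {
  ggplot2::ggplot(object$per_chrom, ggplot2::aes(
    x = .data$subgenome, y = .data$rate, fill = .data$subgenome
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "subgenome", y = "SV per Mbp") +
    ggplot2::theme_minimal()
}
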