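#' Plot a copy-number profile with optional segment means
#'
#' Scatter of per-bin copy number along the genome, faceted by
#' chromosome, with merged segment means overlaid when calls are given
#' (gains red, losses blue, the field's usual palette).
#'
#' @param profile Normalized profile with `cn` (one sample).
#' @param calls Optional `cna_calls` object for the same sample.
#' @param layout A `genome_layout`.
#' @return A ggplot object.
#' @export
plot_cn_profile <- function(profile, layout, calls = NULL) {
  grid <- build_bin_grid(layout)
  p <- dplyr::arrange(profile, match(.data$chrom, layout$chrom),
                      .data$start)
  p$usable <- grid$usable
  g <- ggplot2::ggplot(p[p$usable, ],
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = .data$cn)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, colour = "grey40") +
    ggplot2::facet_grid(~factor(chrom, levels = layout$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copy number") +
    ggplot2::theme_bw()
  if (!is.null(calls)) {
    segs <- calls$segments
    g <- g + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                   y = .data$mean_cn_sample,
                   yend = .data$mean_cn_sample,
                   colour = .data$state),
      linewidth = 1.1, inherit.aes = FALSE) +
      ggplot2::scale_colour_manual(
        values = c(E = "black", G = "#c0392b", L = "#2e6da4",
                   i = "grey70"))
  }
  g
}

#' Heatmap of per-arm gain/loss frequencies
#'
#' Arm frequencies ([frequency_table()]) as signed percentages: gains
#' plotted upward in red, losses downward in blue, one tile per arm and
#' group.
#'
#' @param freq Output of [frequency_table()].
#' @param group Column to place on the y axis (default `"day"`).
#' @return A ggplot object.
#' @export
plot_arm_frequencies <- function(freq, group = "day") {
  freq$arm_label <- paste0(freq$chrom, freq$arm)
  freq$signed <- ifelse(freq$direction == "gain", freq$pct, -freq$pct)
  ggplot2::ggplot(freq, ggplot2::aes(
    x = factor(.data$arm_label, levels = unique(.data$arm_label)),
    y = factor(.data[[group]]), fill = .data$signed)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~direction, ncol = 1) +
    ggplot2::scale_fill_gradient2(low = "#2e6da4", mid = "white",
                                  high = "#c0392b",
                                  name = "% populations") +
    ggplot2::labs(x = "chromosome arm", y = group) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' CNA-type proportions over time
#'
#' Line plot of the whole-chromosome / arm / focal event shares by day
#' ([cna_type_proportions()]).
#'
#' @param proportions Output of [cna_type_proportions()].
#' @return A ggplot object.
#' @export
plot_cna_type_trends <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$day, y = .data$pct,
                               colour = .data$scope)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "% of CNAs", colour = "CNA type") +
    ggplot2::theme_bw()
}
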