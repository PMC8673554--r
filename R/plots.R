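# ggplot2 views of the main result types.

#' Chromosomal differential-expression plot
#'
#' Genes on the locus chromosome plotted at their genomic center with the
#' log2 fold change (mutant vs wild-type) on the y-axis; non-significant
#' genes grey, significant up-regulated green, down-regulated red. The
#' locus is shaded.
#'
#' @param de A `fusegraph_de` result from [chromosomal_de()].
#' @return A ggplot object.
#' @export
plot_chromosomal_de <- function(de) {
  locus <- attr(de, "locus")
  p <- ggplot2::ggplot(tidy(de),
                       ggplot2::aes(x = .data$genomic_center,
                                    y = .data$logFC,
                                    colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60")
  if (!is.null(locus)) {
    p <- p + ggplot2::annotate("rect", xmin = locus$start, xmax = locus$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.08,
                               fill = "grey20")
  }
  p +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#1b9e3a", down = "#d62728", ns = "grey65"),
      breaks = c("up", "down", "ns")
    ) +
    ggplot2::labs(
      x = paste0("genomic center on ", de$chrom[1], " (bp)"),
      y = "log2 fold change (mutant vs wild-type)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot fusegraph_de
#' @export
autoplot.fusegraph_de <- function(object, ...) plot_chromosomal_de(object)

#' Binned junction-density chromosome plot
#'
#' @param bins Output of [bin_junction_density()].
#' @return A ggplot object, one panel per contig, one line per track.
#' @export
plot_junction_density <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_start, y = .data$count,
                                     colour = .data$track)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "junction endpoints per bin",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
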