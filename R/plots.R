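# ggplot2 views of the main result types.

#' Plot a permutation null against the observed statistic
#'
#' Histogram of the permutation draws with the observed value as a
#' vertical line.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic_name, y = "permutation trials",
      title = sprintf("observed %s vs %d-trial null (p = %.3g)",
                      object$statistic_name, object$n_permutations,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Genome overview of detected islands
#'
#' One horizontal bar per chromosome with detected islands drawn as
#' segments, shaded by pervasiveness.
#'
#' @param object A `di_result`.
#' @param genome Genome layout used for the scan.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot di_result
#' @export
autoplot.di_result <- function(object, genome, ...) {
  isl <- object$islands
  isl$chrom_f <- factor(isl$chrom, levels = rev(genome$chrom))
  gdf <- genome
  gdf$chrom_f <- factor(gdf$chrom, levels = rev(genome$chrom))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = gdf,
      ggplot2::aes(x = 0, xend = .data$length / 1e6,
                   y = .data$chrom_f, yend = .data$chrom_f),
      colour = "grey80", linewidth = 2) +
    ggplot2::geom_segment(
      data = isl,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$chrom_f, yend = .data$chrom_f,
                   colour = .data$pervasiveness),
      linewidth = 4) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  colour = "pervasiveness",
                  title = "Divergence islands along the genome") +
    ggplot2::theme_minimal()
}

#' Histogram of same-chromosome island pair distances
#'
#' @param islands Tibble `chrom`, `start`, `end`.
#' @param bin_width Bin width in bp (200 Kb).
#' @return A ggplot object.
#' @export
plot_pair_gaps <- function(islands, bin_width = 200000) {
  df <- pair_gap_distribution(islands, bin_width)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                                   y = .data$n_pairs)) +
    ggplot2::geom_col(width = bin_width / 1e6, fill = "grey60") +
    ggplot2::labs(x = "pair distance (Mb)", y = "island pairs",
                  title = "Distances between same-chromosome island pairs") +
    ggplot2::theme_minimal()
}
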