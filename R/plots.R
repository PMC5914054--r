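#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synteny block map
#'
#' Draws each genome's chromosomes as horizontal tracks with blocks as
#' segments, coloured by block id so conserved blocks can be traced across
#' genomes; `-` blocks are drawn below the chromosome line.
#'
#' @param object A `synteny_blocks` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synteny_blocks <- function(object, ...) {
  df <- dplyr::mutate(object$blocks,
                      y = ifelse(.data$sign == "+", 0.15, -0.15),
                      block = factor(.data$block_id))
  ggplot2::ggplot(df) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$block),
                          linewidth = 3) +
    ggplot2::facet_grid(genome ~ seq, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "block") +
    ggplot2::scale_y_continuous(limits = c(-0.5, 0.5), breaks = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed block lengths against the random-breakage null
#'
#' Density of the null block-length distribution with the observed lengths
#' overlaid per genome; dashed lines mark the comparison percentile in each
#' sample (the quantities behind the exceedance verdict).
#'
#' @param object A `breakage_comparison` from [compare_largest_blocks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breakage_comparison <- function(object, ...) {
  obs <- attr(object, "observed")
  nul <- attr(object, "null")
  ggplot2::ggplot() +
    ggplot2::geom_density(data = nul,
                          ggplot2::aes(x = .data$length / 1e3),
                          fill = "grey80", colour = "grey50") +
    ggplot2::geom_rug(data = obs,
                      ggplot2::aes(x = .data$length / 1e3,
                                   colour = .data$genome)) +
    ggplot2::geom_vline(xintercept = object$null_p[1] / 1e3,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::geom_vline(data = object,
                        ggplot2::aes(xintercept = .data$observed_p / 1e3,
                                     colour = .data$genome),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "block length (kb)", y = "null density",
                  colour = "genome") +
    ggplot2::theme_minimal()
}
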