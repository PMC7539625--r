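# ggplot2 graphics for the pipeline's result types.

#' Empirical cumulative coverage curve
#'
#' Fraction of the locus covered at or above each depth, from the phase
#' pileup.
#'
#' @param phase An `ig_phase`.
#' @param max_depth Right edge of the depth axis (default: observed max).
#' @return A ggplot object.
#' @export
plot_coverage <- function(phase, max_depth = NULL) {
  depth <- colSums(phase$pileup[1:4, , drop = FALSE])
  md <- max_depth %||% max(depth)
  dd <- tibble(depth = seq(0, md),
               fraction = vapply(seq(0, md), function(t) mean(depth >= t), 0))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$depth, y = .data$fraction)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::labs(x = "CCS read depth", y = "fraction of locus at or above depth",
                  title = "Empirical cumulative coverage") +
    ggplot2::theme_minimal()
}

#' Haplotype-block map
#'
#' Blocks along the locus, coloured by class, with phased SNV counts.
#'
#' @param phase An `ig_phase`.
#' @return A ggplot object.
#' @export
plot_blocks <- function(phase) {
  b <- phase$blocks
  ggplot2::ggplot(b) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                                    ymin = 0, ymax = 1, fill = .data$class),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(heterozygous = "#4477AA",
                                          homozygous_or_hemizygous = "#DDCC77")) +
    ggplot2::labs(x = "position (kb)", y = NULL, title = "Haplotype blocks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Multiplex sweep metrics
#'
#' Recall and false-positive rate against the ground-truth run per plex
#' level.
#'
#' @param sweep Tibble from [multiplex_sweep()].
#' @return A ggplot object.
#' @export
plot_multiplex <- function(sweep) {
  dd <- sweep %>%
    mutate(plex_n = as.integer(sub("^plex", "", .data$plex))) %>%
    tidyr::pivot_longer(c("recall_gt", "fp_rate_gt"), names_to = "metric")
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$plex_n, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "multiplex level (samples per run)", y = NULL,
                  title = "Effect of multiplexing on SNV calling") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ig_comparison <- function(object, ...) {
  dd <- tibble(category = c("TP", "FP", "FN", "discordant"),
               n = c(object$tp, object$fp, object$fn,
                     object$genotype_discordant))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "SNVs", title = "Call-set comparison") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
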