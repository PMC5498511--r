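#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot prediction accuracy by marker panel
#'
#' Mean validation accuracy per panel with +/- 1 SD error bars, coloured
#' by model and faceted by QTL count and heritability.
#'
#' @param object an `accuracy_table` from [run_scenario()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accuracy_table <- function(object, ...) {
  tab <- tibble::as_tibble(object) |>
    dplyr::mutate(panel = factor(.data$panel, levels = paste0("mp", 1:7)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$panel, y = .data$mean_accuracy,
                                    colour = .data$model,
                                    group = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(ggplot2::vars(.data$h2), ggplot2::vars(.data$n_qtl),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "marker panel", y = "validation accuracy (r)",
                  colour = "model") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Plot the LD profile of a marker panel's loci against their QTL
#'
#' Histogram of the maximum r-squared each selected marker shows with any
#' QTL; a quick diagnostic of how tightly a panel tags the architecture.
#'
#' @param mp a `marker_panel` from [build_panel()].
#' @param arch the [sample_architecture()] it was built from.
#' @param panel the [genotype_panel()].
#' @return a ggplot object.
#' @export
plot_panel_ld <- function(mp, arch, panel) {
  r2 <- r2_matrix(panel, arch$qtl_index)
  best <- apply(r2[, mp$locus_index, drop = FALSE], 2, max, na.rm = TRUE)
  ggplot2::ggplot(tibble::tibble(r2 = best), ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(x = expression(max~r^2~with~a~QTL), y = "markers",
                  title = paste0(attr(mp, "name"), " (", nrow(mp), " loci)")) +
    ggplot2::theme_bw()
}
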