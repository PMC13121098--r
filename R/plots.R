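#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an effect map
#'
#' Per-region group t statistics (or session-change coefficients),
#' coloured by functional network, with the uncorrected p < 0.05 regions
#' emphasised — a flat-file analogue of the usual brain-surface effect
#' panels.
#'
#' @param object An `effect_map` tibble.
#' @param atlas Atlas tibble supplying region names and networks.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_map <- function(object, atlas = default_atlas(), ...) {
  d <- dplyr::inner_join(tibble::as_tibble(object), atlas, by = "region_id")
  d$stat <- ifelse(d$contrast == "session_change", d$coefficient, d$t_value)
  d$sig <- !is.na(d$p_value) & d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region_id, y = .data$stat,
                                  colour = .data$network,
                                  alpha = .data$sig)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_grid(contrast ~ metric) +
    ggplot2::labs(x = "region", y = "group t / session coefficient",
                  colour = "network") +
    ggplot2::theme_minimal()
}

#' Plot a cross-modal correlation table
#'
#' Heat-tile grid of Spearman correlations between effect maps for each
#' metric pair and contrast; significant (uncorrected permutation
#' p < 0.05) cells are outlined.
#'
#' @param object A `crossmodal_tbl` from [crossmodal_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmodal_tbl <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$pair <- paste(d$metric_1, d$metric_2, sep = " ~ ")
  d$sig <- d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contrast, y = .data$pair,
                                  fill = .data$rho)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$sig),
                       linewidth = 0.8, width = 0.95, height = 0.95) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("r=%.2f\np=%.3f", .data$rho, .data$p_value)),
      size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey85",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::facet_wrap(~subset) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal()
}

#' Plot regional metric maps
#'
#' Distribution of a regional metric by group and session.
#'
#' @param metrics A metric-map tibble.
#' @param manifest A validated manifest tibble.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(metrics, manifest) {
  covs <- dplyr::distinct(manifest, .data$subject_id, .data$group)
  d <- dplyr::inner_join(metrics, covs, by = "subject_id")
  d$cell <- paste0(d$group, " s", d$session)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "regional value") +
    ggplot2::theme_minimal()
}
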