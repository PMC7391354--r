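#' Plot a per-feature reliability table
#'
#' Point estimates with bootstrap CIs, grouped by feature category and
#' sorted by ICC within category; the customary 0.8 and 0.9 reproducibility
#' cut-offs are drawn as reference lines.
#'
#' @param object an `icc_tbl` from [icc_table()]
#' @param thresholds reference lines to draw
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.icc_tbl <- function(object, thresholds = c(0.8, 0.9), ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$icc), , drop = FALSE]
  d <- dplyr::arrange(d, .data$category, .data$icc)
  d$feature <- factor(d$feature, levels = d$feature)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$icc,
                                  colour = .data$category)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(. ~ category, scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none") +
    ggplot2::labs(x = "feature (sorted by ICC within category)",
                  y = "ICC(1,1)")
}

#' Plot a pairwise Dice matrix as a heatmap
#'
#' @param object a `dice_matrix` from [pairwise_dice()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.dice_matrix <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(unclass(object),
                                    .name_repair = "minimal"),
                  .row = rownames(object) %||% as.character(seq_len(nrow(object)))),
    -".row", names_to = ".col", values_to = "dice")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.col, y = .data$.row,
                                  fill = .data$dice)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Dice")
}

#' Plot per-category mean ICCs
#'
#' @param summary a tibble from [category_summary()]
#' @return a ggplot
#' @export
plot_category_summary <- function(summary) {
  d <- summary[summary$category != "overall", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$category,
                                                     -.data$mean_icc),
                                  y = .data$mean_icc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "feature category", y = "mean ICC(1,1)")
}

#' Scatter of paired ICCs from two rater populations
#'
#' @param object an `icc_comparison` from [compare_icc()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.icc_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$icc_a,
                                            y = .data$icc_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "ICC (population A)", y = "ICC (population B)",
      subtitle = sprintf("Pearson r = %.3f over %d features",
                         object$pearson_r, object$n_features))
}
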