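# ggplot2 presentation of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA sample scores
#'
#' Scatter of the first two principal components with the explained
#' variance of each component in the axis labels.
#'
#' @param object A `glyco_pca` object from [pca_scores()].
#' @param design Optional design tibble (`sample`, `condition`) used to
#'   colour points by condition.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glyco_pca
#' @export
autoplot.glyco_pca <- function(object, design = NULL, ...) {
  d <- object$scores
  if (!is.null(design)) d <- dplyr::left_join(d, design, by = "sample")
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i, 100 * object$explained[i])
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_bw()
  if (!is.null(design)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$condition),
                            size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Volcano plot of a differential contrast
#'
#' @param object A `glyco_contrast` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glyco_contrast
#' @export
autoplot.glyco_contrast <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_bw()
}

#' Site-specific glycoform profile bar chart
#'
#' Mean relative abundance of each glycoform per condition with
#' replicate standard deviations, one panel per site-peptide family —
#' the standard way to display shifts in site occupancy and glycan
#' size between conditions.
#'
#' @param profiles Glycoform profile tibble from
#'   [glycoform_fractions()].
#' @param design Design tibble (`sample`, `condition`).
#' @return A ggplot object.
#' @export
plot_glycoform_profile <- function(profiles, design) {
  d <- profiles |>
    dplyr::inner_join(design, by = "sample") |>
    dplyr::group_by(.data$family, .data$glycoform, .data$condition) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction, na.rm = TRUE),
      sd_fraction = stats::sd(.data$fraction, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$glycoform, .data$mean_fraction,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "relative abundance") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
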