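#' Volcano plot of a differential-expression result
#'
#' -log10(P) against log2 fold change, significant up/down circles
#' highlighted at the fitted thresholds.
#'
#' @param object A `circ_de` tibble from [differential()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.circ_de <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(neglog10p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neglog10p,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue",
                 unchanged = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(attr(object,
                                                          "fc_cutoff")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (old / young)",
                  y = "-log10 P",
                  title = sprintf("Differential circRNA expression (%s)",
                                  attr(object, "tissue"))) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object A `circ_pca` from [pca_expression()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.circ_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$tissue,
                               shape = .data$age)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])) +
    ggplot2::theme_minimal()
}

#' Circular-versus-linear fold-change cloud
#'
#' Scatter/density of per-circle (log2 linear FC, log2 circ FC) pairs; a
#' cloud shifted on the y-axis only is the signature of host-independent
#' circRNA accumulation.
#'
#' @param object A `circ_independence` from [circ_linear_independence()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.circ_independence <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$log2_fc_linear,
                               y = .data$log2_fc_circ)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_density_2d(colour = "steelblue") +
    ggplot2::labs(x = "log2 linear FC (old / young)",
                  y = "log2 circRNA FC (old / young)") +
    ggplot2::theme_minimal()
}
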