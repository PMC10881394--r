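# ggplot2 views of each result type.

#' @exportS3Method
autoplot.induction_clustering <- function(object, ...) {
  m <- object$matrix[object$row_order, object$col_order, drop = FALSE]
  df <- as_tibble(m, rownames = "stimulation") %>%
    tidyr::pivot_longer(-"stimulation", names_to = "cytokine",
                        values_to = "slmd") %>%
    mutate(stimulation = factor(.data$stimulation, levels = rev(object$row_order)),
           cytokine = factor(.data$cytokine, levels = object$col_order))
  ggplot2::ggplot(df, ggplot2::aes(.data$cytokine, .data$stimulation,
                                   fill = .data$slmd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "SLMD",
                  title = "Standardized log mean differences") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method
autoplot.cytovar_screen <- function(object, ...) {
  df <- object$results
  if (!nrow(df)) return(ggplot2::ggplot())
  ggplot2::ggplot(df, ggplot2::aes(.data$cytokine, .data$variable,
                                   fill = -log10(.data$p_adjusted))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df %>% filter(.data$significant),
                        shape = 8, size = 1) +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = expression(-log[10] ~ "adj. p"),
      title = sprintf("Variable screen: %s", object$stimulation),
      subtitle = sprintf("* BY-adjusted p < %g", object$alpha)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Effect-size plot
#'
#' Exponentiated coefficients with confidence intervals, one row per
#' level; significant levels (coefficient t-test p below the threshold
#' used in [effect_sizes()]) drawn solid, others greyed.
#'
#' @param effects Tibble from [effect_sizes()].
#' @return A ggplot.
#' @export
plot_effect_sizes <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(.data$exp_estimate, .data$term,
                                        colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey65"),
                                 guide = "none") +
    ggplot2::labs(x = "Multiplicative effect on concentration (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.cytovar_varpart <- function(object, ...) {
  df <- object$shares %>% mutate(response = object$response)
  ggplot2::ggplot(df, ggplot2::aes(.data$response, 100 * .data$share,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Variance explained (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked variance-share plot for a stimulation
#'
#' @param report Tibble from [variance_report()].
#' @return A ggplot with one stacked bar per cytokine.
#' @export
plot_variance_shares <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(.data$cytokine, 100 * .data$share,
                                       fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Variance explained (%)", fill = NULL,
                  title = unique(report$stimulation)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method
autoplot.cytokine_pca <- function(object, colour = NULL, ...) {
  vf <- object$variance$var_fraction
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[2])
    ) +
    ggplot2::theme_minimal()
}
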