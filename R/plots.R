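#' @export
autoplot.kernel_model <- function(object, ...) {
  df <- tidy(object, type = "kernels")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$value,
                                   colour = .data$input)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Lag (s)", y = sprintf("Kernel (%s units per input unit)", object$output),
      colour = "Input",
      title = sprintf("Estimated kernels, output %s (NMSE = %.3f)",
                      object$output, object$nmse)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pdm_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value,
                                   colour = .data$mode)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag", y = "Mode value", colour = "Mode",
                  title = paste0("Principal dynamic modes",
                                 if (!is.null(object$pathway))
                                   paste0(" (", object$pathway, ")") else "")) +
    ggplot2::theme_minimal()
}

#' Group distributions of the hemodynamic indices
#'
#' Boxplots (with jittered points) of each log-likelihood-ratio index by
#' cognitive group.
#'
#' @param data Tibble containing the index columns and a group column.
#' @param indices Index columns to show.
#' @param group Grouping column name.
#' @return A ggplot object.
#' @export
plot_index_groups <- function(data,
                              indices = c("DVR", "DCA", "COCR", "COPR", "composite_COR"),
                              group = "diagnosis") {
  df <- tidyr::pivot_longer(
    data[, c(group, intersect(indices, names(data)))],
    -dplyr::all_of(group), names_to = "index", values_to = "value"
  )
  df$index <- factor(df$index, levels = indices)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data$value,
                                   fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.5) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Index (log-likelihood-ratio scale)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.assoc_table <- function(object, ...) {
  df <- object[!is.na(object$beta), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$predictor,
                                   colour = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "Standardized beta (95% CI)", y = NULL,
                  colour = "At Bonferroni threshold") +
    ggplot2::theme_minimal()
}
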