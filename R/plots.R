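# ggplot2 views of the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot per-well top-K mean sizes by condition
#'
#' Dot plot of well-level mean top-K colonoid areas per condition, one facet
#' per oxygen level when present, with the per-group mean marked.
#'
#' @param summaries tibble of well summaries with key columns (condition,
#'   optionally oxygen/donor) and `mean_top_k_area`.
#' @return A ggplot object.
#' @export
plot_well_summaries <- function(summaries) {
  p <- ggplot2::ggplot(summaries,
                       ggplot2::aes(x = .data$condition,
                                    y = .data$mean_top_k_area)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red3") +
    ggplot2::labs(x = NULL, y = "mean top-K colonoid area (µm²)") +
    ggplot2::theme_bw()
  if ("oxygen" %in% names(summaries)) {
    p <- p + ggplot2::facet_wrap(~oxygen, labeller = ggplot2::label_both)
  }
  p
}

#' Plot analyte concentrations by condition
#'
#' Violin + jitter of panel concentrations per condition, faceted by analyte,
#' log10 y-scale (concentrations are log-normally distributed).
#'
#' @param panel preprocessed panel tibble (`analyte`, `condition`, `value`).
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  ggplot2::ggplot(dplyr::filter(panel, !is.na(.data$value)),
                  ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "concentration (pg/mL)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of mixed-model fixed effects
#'
#' @param object an `lmm_fit`.
#' @param ... unused.
#' @return A ggplot object: estimates with approximate 95% intervals
#'   (+- 1.96 standard errors), intercept omitted.
#' @export
autoplot.lmm_fit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::labs(x = "effect on log concentration", y = NULL) +
    ggplot2::theme_bw()
}
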