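#' Plot per-subfamily activity estimates
#'
#' Point estimates with confidence bars on the log2-activity scale,
#' subfamilies ordered by estimate; subfamilies passing the adjusted-p
#' significance threshold are highlighted.
#'
#' @param object A `te_activity_fit`.
#' @param level Confidence level for the bars, default 0.95.
#' @param alpha Significance threshold on the adjusted p-value, default
#'   0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.te_activity_fit <- function(object, level = 0.95, alpha = 0.05, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  df <- object$table %>%
    dplyr::mutate(
      low = .data$estimate - z * .data$std_error,
      high = .data$estimate + z * .data$std_error,
      significant = .data$adj_p_value <= alpha
    ) %>%
    dplyr::arrange(.data$estimate) %>%
    dplyr::mutate(subfamily = factor(.data$subfamily, levels = .data$subfamily))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subfamily, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                           width = 0, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                                 name = sprintf("adj. p <= %.2g", alpha)) +
    ggplot2::labs(x = NULL,
                  y = expression(Delta * "A (log2 expression per integrant)")) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot cross-validation error against bandwidth
#'
#' Mean validation RMSE per candidate bandwidth (log10 x-axis) with the
#' per-fold values overlaid; the selected bandwidth is marked.
#'
#' @param object A `bandwidth_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bandwidth_cv <- function(object, ...) {
  pf <- object$per_fold[is.finite(object$per_fold$rmse), , drop = FALSE]
  mr <- object$mean_rmse[is.finite(object$mean_rmse$rmse), , drop = FALSE]
  ggplot2::ggplot(mr, ggplot2::aes(x = .data$L, y = .data$rmse)) +
    ggplot2::geom_point(data = pf, colour = "grey70", size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$selected_L, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bandwidth L (bp)", y = "mean validation RMSE") +
    ggplot2::theme_minimal()
}
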