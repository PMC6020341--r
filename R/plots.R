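#' Mean-CV2 relationship plot
#'
#' Scatter of per-gene CV2 against mean log2 expression with the fitted
#' reciprocal expectation overlaid, the standard diagnostic for the
#' mean-adjustment step.
#'
#' @param noise Noise tibble; if it carries `expected_cv2` (from
#'   [residual_cv2()]) the fitted curve is drawn.
#' @return A ggplot object.
#' @export
plot_mean_cv2 <- function(noise) {
  p <- ggplot2::ggplot(
    dplyr::filter(noise, is.finite(.data$mu), is.finite(.data$cv2)),
    ggplot2::aes(x = .data$mu, y = .data$cv2)
  ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(
      x = expression(mu ~ "(log2 mean normalized count)"),
      y = expression(CV^2)
    ) +
    ggplot2::theme_minimal()
  if ("expected_cv2" %in% names(noise)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(
        noise, is.finite(.data$expected_cv2), .data$expected_cv2 > 0
      ) |> dplyr::arrange(.data$mu),
      ggplot2::aes(y = .data$expected_cv2),
      colour = "orange", linewidth = 1
    )
  }
  p
}

#' Feature-screen coefficient plot
#'
#' Dot plot of robust-regression coefficients per feature, univariate and
#' multivariate side by side; non-significant features are greyed.
#'
#' @param screen Long screen tibble from [univariate_screen()] /
#'   [multivariate_screen()] (rows may be concatenated).
#' @return A ggplot object.
#' @export
plot_screen <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(
    x = .data$feature, y = .data$beta,
    shape = .data$model_kind, colour = .data$significant
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(
      size = 3,
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#d95f02", `FALSE` = "grey60")
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(beta ~ "(effect on rCV"^2 * ")")) +
    ggplot2::theme_minimal()
}

#' Promoter chromatin classification plot
#'
#' H3K4me3 against H3K27me3 promoter signal, coloured by assigned class,
#' with the multiplier-scaled thresholds drawn.
#'
#' @param classes `promoter_chromatin` tibble from [classify_bivalency()].
#' @return A ggplot object.
#' @export
plot_chromatin_classes <- function(classes) {
  th <- chromatin_thresholds(classes)
  ggplot2::ggplot(classes, ggplot2::aes(
    x = .data$k4_signal, y = .data$k27_signal, colour = .data$class
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(
      xintercept = th$multiplier * th$k4_threshold, linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = th$multiplier * th$k27_threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "H3K4me3 (log2 enrichment)", y = "H3K27me3 (log2 enrichment)"
    ) +
    ggplot2::theme_minimal()
}

#' Noise by island-size bin and response label
#'
#' Mean pre-stimulation noise per 0.5-kb island-size bin, coloured by the
#' differential-expression label.
#'
#' @param nvr Result of [noise_vs_response()].
#' @return A ggplot object.
#' @export
plot_noise_bins <- function(nvr) {
  ggplot2::ggplot(
    dplyr::filter(nvr$bins, !is.na(.data$mean_noise)),
    ggplot2::aes(
      x = .data$bin_start, y = .data$mean_noise, colour = .data$label
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      up = "#d7301f", down = "#0570b0", nochange = "#fec44f"
    )) +
    ggplot2::labs(
      x = "CpG island size bin (bp)", y = "mean noise", colour = "response"
    ) +
    ggplot2::theme_minimal()
}
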