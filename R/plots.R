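#' Mean angular deviation against feedback rotation
#'
#' Group-mean deviation of each judgment kind as a function of the
#' visual-feedback rotation, with SE bars: the proportional-bias picture.
#' Hand judgments (explicit and, about half as strongly, implicit) tilt
#' with the rotation; cursor judgments tilt slightly against it.
#'
#' @param trials A trial tibble.
#' @param estimates Optional `vp_estimates` to drop excluded participants.
#' @return A ggplot object.
#' @export
plot_deviation_profile <- function(trials, estimates = NULL) {
  prof <- summarize_variability(rotation_profile(trials, estimates))
  ggplot2::ggplot(
    prof,
    ggplot2::aes(.data$rotation_deg, .data$mean_of_means,
                 colour = .data$kind, shape = .data$group)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_of_means - .data$se_of_means,
                   ymax = .data$mean_of_means + .data$se_of_means),
      width = 1.5
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$group)) +
    ggplot2::labs(x = "visual-feedback rotation (deg)",
                  y = "mean angular deviation (deg)",
                  colour = "judgment", shape = "group",
                  linetype = "group") +
    ggplot2::theme_minimal()
}

#' Intra-individual variability by judgment kind and rotation
#'
#' Group means of the per-participant SDs of the angular deviations.
#'
#' @inheritParams plot_deviation_profile
#' @return A ggplot object.
#' @export
plot_variability <- function(trials, estimates = NULL) {
  prof <- summarize_variability(rotation_profile(trials, estimates))
  ggplot2::ggplot(
    prof,
    ggplot2::aes(.data$rotation_deg, .data$mean_sd,
                 colour = .data$kind, shape = .data$group)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_sd - .data$se_sd,
                   ymax = .data$mean_sd + .data$se_sd),
      width = 1.5
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$group)) +
    ggplot2::labs(x = "visual-feedback rotation (deg)",
                  y = "mean intra-individual SD (deg)",
                  colour = "judgment", shape = "group",
                  linetype = "group") +
    ggplot2::theme_minimal()
}

#' Sequential effects on subset biases
#'
#' Group-mean subset biases by preceding explicit-judgment type and its
#' repetition, per judgment kind.
#'
#' @param seq_biases A tibble from [sequential_biases()].
#' @return A ggplot object.
#' @export
plot_sequential_biases <- function(seq_biases) {
  summ <- seq_biases |>
    dplyr::group_by(.data$group, .data$kind, .data$preceding_type,
                    .data$repetition) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      se = stats::sd(.data$slope) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(
    summ,
    ggplot2::aes(.data$repetition, .data$mean_slope,
                 colour = .data$preceding_type,
                 group = .data$preceding_type)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_slope - .data$se,
                   ymax = .data$mean_slope + .data$se),
      width = 0.1
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_grid(.data$kind ~ .data$group, scales = "free_y") +
    ggplot2::labs(x = "repetition of the preceding judgment type",
                  y = "mean subset bias (deg/deg)",
                  colour = "preceding judgment") +
    ggplot2::theme_minimal()
}
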