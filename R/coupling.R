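#' Weighted-average coupled estimate
#'
#' Sensory coupling biases the estimate from one modality toward the signal
#' of the other without fusing the two percepts. The coupled estimate is the
#' weighted average `(1 - b) * own + b * other`, where `b` is the
#' proportional bias toward the other modality (0 = independence, 1 = full
#' capture).
#'
#' @param own Numeric vector: the unbiased own-modality signal (degrees).
#' @param other Numeric vector: the other modality's signal (degrees).
#' @param b Proportional bias in `[0, 1]`.
#' @return Numeric vector of coupled estimates (degrees).
#' @examples
#' coupled_estimate(10, 20, 0)     # own signal
#' coupled_estimate(10, 20, 1)     # full capture
#' coupled_estimate(10, 20, 0.63)  # 16.3
#' @export
coupled_estimate <- function(own, other, b) {
  stopifnot(is.numeric(b), all(b >= 0 & b <= 1))
  (1 - b) * own + b * other
}

#' Relative variance of a coupled estimate
#'
#' For independent zero-mean noises on the own and other signals with
#' variance ratio `r = var(other) / var(own)`, the variance of the coupled
#' estimate relative to the unbiased own-modality variance is
#' \deqn{(1 - b)^2 + b^2 r + 2 b (1 - b) \rho \sqrt{r},}
#' where \eqn{\rho} is the noise correlation (0 by default). The same
#' function serves both directions of the coupling: for the
#' proprioceptive estimate use `r = var(V)/var(P)`, for the visual estimate
#' use the reciprocal ratio.
#'
#' A key property is that a weak coupling reduces variance even for the more
#' precise modality: `relative_variance(b, r) < 1` for all
#' `0 < b < 2 / (1 + r)` (with `rho = 0`).
#'
#' @param b Proportional bias toward the other modality, in `[0, 1]`.
#' @param r Variance ratio var(other)/var(own), `>= 0`.
#' @param rho Correlation between the two noises, in `[-1, 1]`; default 0
#'   (independent noises).
#' @return Relative variance var(coupled)/var(own), unitless.
#' @examples
#' relative_variance(0, 5)      # 1: no coupling
#' relative_variance(1, 0.2)    # 0.2: full capture
#' relative_variance(0.5, 0.2)  # 0.3
#' @export
relative_variance <- function(b, r, rho = 0) {
  stopifnot(all(b >= 0 & b <= 1), all(rho >= -1 & rho <= 1))
  if (any(r < 0)) stop("relative_variance(): r must be >= 0", call. = FALSE)
  (1 - b)^2 + b^2 * r + 2 * b * (1 - b) * rho * sqrt(r)
}

#' Variance-minimizing bias and its minimum relative variance
#'
#' The relative variance `(1 - b)^2 + b^2 r` is strictly convex in `b` with
#' a unique minimum at `b* = 1 / (1 + r)`, where it equals `r / (1 + r)`.
#' This is the coupling strength an observer minimizing the variance of the
#' biased estimate should adopt, and it coincides with the
#' inverse-variance weight of classical cue integration.
#'
#' @param r Variance ratio var(other)/var(own), `>= 0` (vectorized).
#' @return A tibble with columns `r`, `b_opt` and `min_relative_variance`.
#' @examples
#' optimal_bias(c(0, 0.2, 1))
#' @export
optimal_bias <- function(r) {
  if (any(r < 0)) stop("optimal_bias(): r must be >= 0", call. = FALSE)
  tibble::tibble(
    r = r,
    b_opt = 1 / (1 + r),
    min_relative_variance = r / (1 + r)
  )
}

#' Variance-reduction curves of the coupling model
#'
#' Tabulates [relative_variance()] on a grid of biases and variance ratios,
#' for both directions of the coupling: the `proprioceptive` panel plots
#' var(P')/var(P) against the bias toward vision using `r` directly, the
#' `visual` panel plots var(V')/var(V) against the bias toward
#' proprioception using `1/r`. Ready for [plot_coupling_curves()] or CSV
#' export.
#'
#' @param b Numeric vector of biases; default `seq(0, 1, by = 0.01)`.
#' @param r Numeric vector of ratios var(V)/var(P); default
#'   `seq(0.2, 0.7, by = 0.1)`.
#' @return A tibble with columns `panel` (`"proprioceptive"`/`"visual"`),
#'   `b`, `r` (always the ratio var(V)/var(P)) and `relative_variance`.
#' @export
coupling_curves <- function(b = seq(0, 1, by = 0.01),
                            r = seq(0.2, 0.7, by = 0.1)) {
  grid <- tidyr::expand_grid(panel = c("proprioceptive", "visual"), r = r, b = b)
  dplyr::mutate(
    grid,
    relative_variance = relative_variance(
      .data$b,
      ifelse(.data$panel == "proprioceptive", .data$r, 1 / .data$r)
    ),
    .before = 1
  ) |>
    dplyr::select("panel", "b", "r", "relative_variance")
}

#' Plot variance-reduction curves
#'
#' @param curves A tibble from [coupling_curves()]; computed with defaults
#'   when missing.
#' @return A ggplot object: relative variance against bias, one line per
#'   variance ratio, one facet per coupling direction.
#' @export
plot_coupling_curves <- function(curves = coupling_curves()) {
  ggplot2::ggplot(
    curves,
    ggplot2::aes(.data$b, .data$relative_variance,
                 colour = factor(.data$r), group = factor(.data$r))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~ .data$panel) +
    ggplot2::labs(
      x = "proportional bias toward the other modality",
      y = "relative variance of the biased estimate",
      colour = "var(V)/var(P)"
    ) +
    ggplot2::theme_minimal()
}
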