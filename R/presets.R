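#' Rotation angles of the visual feedback
#'
#' The twelve feedback rotations applied to the cursor during the second
#' stroke: 5 to 30 deg in 5-deg steps, clockwise (negative) and
#' counter-clockwise (positive).
#'
#' @return Integer vector of the 12 rotation angles in degrees.
#' @export
rotation_set <- function() {
  c(-30L, -25L, -20L, -15L, -10L, -5L, 5L, 10L, 15L, 20L, 25L, 30L)
}

#' Generative preset for one participant group
#'
#' Bundles the group-level parameters of the trial generator: the linear
#' measurement model for each judgment kind (angular deviation =
#' slope * rotation + intercept + Gaussian noise), motor and return-stroke
#' noise, sequential modulation of the biases by the preceding trial's
#' explicit-judgment type, and occasional gross outliers.
#'
#' Slopes are proportional biases in degrees of deviation per degree of
#' feedback rotation; intercepts and SDs are in degrees. The sequential
#' deltas are bias-*strength* increments: after a preceding explicit
#' judgment of the same type, the explicit-judgment bias gets stronger by
#' `seq_delta_explicit_same` (more positive for hand judgments, more
#' negative for cursor judgments); after a preceding explicit *hand*
#' judgment, the implicit-judgment slope changes by
#' `seq_delta_implicit_after_hand` (negative = weaker coupling). Both deltas
#' are multiplied by `repetition_multiplier` when the preceding type had
#' just occurred two or more times in a row.
#'
#' @param group Group label, `"young"` or `"older"`.
#' @param n_participants Number of participants to simulate.
#' @param slope_hand_explicit,slope_cursor_explicit,slope_hand_implicit
#'   Proportional biases (deg/deg).
#' @param intercept_hand_explicit,intercept_cursor_explicit,intercept_implicit
#'   Offsets independent of the rotation (deg); only the explicit hand
#'   judgment has a CCW offset by default.
#' @param sd_hand_explicit,sd_cursor_explicit,sd_implicit Trial-to-trial
#'   judgment noise SDs (deg).
#' @param sd_motor SD of the aiming error of the second stroke (deg).
#' @param return_length_cv Coefficient of variation of the return-stroke
#'   length (unitless).
#' @param seq_delta_explicit_same,seq_delta_implicit_after_hand Sequential
#'   bias-strength increments (deg/deg).
#' @param repetition_multiplier Amplification of the sequential deltas after
#'   a repeated (run length >= 2) preceding judgment type.
#' @param outlier_rate Probability that a trial's judged deviation is
#'   grossly off; must be `< 0.1`.
#' @param outlier_shift Magnitude of the gross shift (deg), random sign.
#' @return An object of class `vp_preset` (a named list).
#' @seealso [young_preset()], [older_preset()], [default_presets()]
#' @export
coupling_preset <- function(group = c("young", "older"),
                            n_participants = 16L,
                            slope_hand_explicit = 0.63,
                            slope_cursor_explicit = -0.08,
                            slope_hand_implicit = 0.31,
                            intercept_hand_explicit = 3,
                            intercept_cursor_explicit = 0,
                            intercept_implicit = 0,
                            sd_hand_explicit = 10,
                            sd_cursor_explicit = 4,
                            sd_implicit = 4,
                            sd_motor = 4,
                            return_length_cv = 0.05,
                            seq_delta_explicit_same = 0.015,
                            seq_delta_implicit_after_hand = -0.015,
                            repetition_multiplier = 2,
                            outlier_rate = 0.005,
                            outlier_shift = 40) {
  group <- match.arg(group)
  p <- list(
    group = group,
    n_participants = as.integer(n_participants),
    slope_hand_explicit = slope_hand_explicit,
    slope_cursor_explicit = slope_cursor_explicit,
    slope_hand_implicit = slope_hand_implicit,
    intercept_hand_explicit = intercept_hand_explicit,
    intercept_cursor_explicit = intercept_cursor_explicit,
    intercept_implicit = intercept_implicit,
    sd_hand_explicit = sd_hand_explicit,
    sd_cursor_explicit = sd_cursor_explicit,
    sd_implicit = sd_implicit,
    sd_motor = sd_motor,
    return_length_cv = return_length_cv,
    seq_delta_explicit_same = seq_delta_explicit_same,
    seq_delta_implicit_after_hand = seq_delta_implicit_after_hand,
    repetition_multiplier = repetition_multiplier,
    outlier_rate = outlier_rate,
    outlier_shift = outlier_shift
  )
  validate_preset(p)
  structure(p, class = "vp_preset")
}

validate_preset <- function(p) {
  sds <- c(p$sd_hand_explicit, p$sd_cursor_explicit, p$sd_implicit, p$sd_motor)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("preset: all noise SDs must be non-negative and finite",
         call. = FALSE)
  }
  slopes <- c(p$slope_hand_explicit, p$slope_cursor_explicit,
              p$slope_hand_implicit)
  if (any(!is.finite(slopes))) {
    stop("preset: slopes must be finite", call. = FALSE)
  }
  if (p$outlier_rate < 0 || p$outlier_rate >= 0.1) {
    stop("preset: outlier_rate must be in [0, 0.1)", call. = FALSE)
  }
  if (p$n_participants < 1) {
    stop("preset: n_participants must be >= 1", call. = FALSE)
  }
  if (p$return_length_cv < 0) {
    stop("preset: return_length_cv must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.vp_preset <- function(x, ...) {
  cat("<vp_preset> group:", x$group, " n =", x$n_participants, "\n")
  cat(sprintf("  slopes (deg/deg): hand-explicit %+0.2f, cursor-explicit %+0.2f, hand-implicit %+0.2f\n",
              x$slope_hand_explicit, x$slope_cursor_explicit,
              x$slope_hand_implicit))
  cat(sprintf("  intercepts (deg): %+0.1f / %+0.1f / %+0.1f;  SDs (deg): %.1f / %.1f / %.1f\n",
              x$intercept_hand_explicit, x$intercept_cursor_explicit,
              x$intercept_implicit, x$sd_hand_explicit, x$sd_cursor_explicit,
              x$sd_implicit))
  cat(sprintf("  sequential deltas: explicit-same %+0.3f, implicit-after-hand %+0.3f (x%.1f when repeated)\n",
              x$seq_delta_explicit_same, x$seq_delta_implicit_after_hand,
              x$repetition_multiplier))
  invisible(x)
}

#' Default preset for the young group
#'
#' Group-mean proportional biases 0.63 (explicit hand), -0.08 (explicit
#' cursor) and 0.31 (implicit), a +3 deg CCW offset of the explicit hand
#' judgments only, and the largest judgment noise for the explicit hand
#' judgments. 16 participants (the retained young sample).
#'
#' @param ... Overrides passed to [coupling_preset()].
#' @return A `vp_preset`.
#' @export
young_preset <- function(...) {
  args <- utils::modifyList(
    list(group = "young", n_participants = 16L,
         slope_hand_explicit = 0.63, slope_cursor_explicit = -0.08,
         slope_hand_implicit = 0.31, sd_hand_explicit = 10),
    list(...)
  )
  do.call(coupling_preset, args)
}

#' Default preset for the older group
#'
#' Group-mean proportional biases 0.75 (explicit hand), -0.07 (explicit
#' cursor) and 0.30 (implicit); explicit-hand judgment noise smaller than in
#' the young group (the age-related variability decline is specific to that
#' judgment). 19 participants (the retained older sample).
#'
#' @param ... Overrides passed to [coupling_preset()].
#' @return A `vp_preset`.
#' @export
older_preset <- function(...) {
  args <- utils::modifyList(
    list(group = "older", n_participants = 19L,
         slope_hand_explicit = 0.75, slope_cursor_explicit = -0.07,
         slope_hand_implicit = 0.30, sd_hand_explicit = 8),
    list(...)
  )
  do.call(coupling_preset, args)
}

#' Default two-group study presets
#'
#' @return A named list with the `young` and `older` default presets
#'   (16 + 19 participants).
#' @export
default_presets <- function() {
  list(young = young_preset(), older = older_preset())
}

#' Read or write presets as YAML
#'
#' @param path File path.
#' @return `read_presets()` returns a named list of `vp_preset` objects;
#'   `write_presets()` returns `path` invisibly.
#' @export
read_presets <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) do.call(coupling_preset, p))
}

#' @rdname read_presets
#' @param presets Named list of `vp_preset` objects.
#' @export
write_presets <- function(presets, path) {
  yaml::write_yaml(lapply(presets, unclass), path)
  invisible(path)
}
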