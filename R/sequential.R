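#' Classify trials by their explicit-judgment history
#'
#' Each trial from the second one onward falls in one of four categories
#' defined by the preceding trial: which explicit judgment it required
#' (`hand` or `cursor`), and whether that type was a repetition, i.e. had
#' just occurred in a run of two or more consecutive trials (`repeated`)
#' or only once (`once`). The first trial of a session has no history and
#' gets `NA`; the second trial is necessarily `once`.
#'
#' @param types Character vector of explicit-judgment types (`"hand"` /
#'   `"cursor"`) in session order, gap-free.
#' @param run_threshold Minimum run length of the preceding same-type run
#'   to count as `repeated`; default 2.
#' @return A tibble with columns `preceding_type` and `repetition`
#'   (`"once"`/`"repeated"`), one row per trial.
#' @examples
#' classify_history(c("cursor", "hand", "hand", "cursor", "hand"))
#' @export
classify_history <- function(types, run_threshold = 2L) {
  n <- length(types)
  if (n == 0L) stop("classify_history(): empty sequence", call. = FALSE)
  # run length of the same-type run ending at each trial
  run <- integer(n)
  run[1] <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      run[i] <- if (types[i] == types[i - 1L]) run[i - 1L] + 1L else 1L
    }
  }
  preceding_type <- c(NA_character_, types[-n])
  prev_run <- c(NA_integer_, run[-n])
  tibble::tibble(
    preceding_type = preceding_type,
    repetition = ifelse(is.na(prev_run), NA_character_,
                        ifelse(prev_run >= run_threshold, "repeated", "once"))
  )
}

#' Append sequential-category columns to a trial table
#'
#' @param trials A trial tibble in session order within participants.
#' @param run_threshold Passed to [classify_history()].
#' @return `trials` with `preceding_type` and `repetition` columns.
#' @export
add_history <- function(trials, run_threshold = 2L) {
  trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$trial_idx, .by_group = TRUE) |>
    dplyr::mutate(classify_history(.data$judgment_type, run_threshold)) |>
    dplyr::ungroup()
}

#' Subset biases by sequential category
#'
#' Fits the bias regression ([fit_bias()]) separately within each
#' (participant, judgment kind, preceding type, repetition) subset of
#' trials. Subsets with fewer than three distinct rotations are dropped
#' with a warning. Slopes are returned with their natural sign; for a
#' strength-based ANOVA flip the cursor-explicit sign with
#' `strength = TRUE`, which adds a `strength` column (`-slope` for
#' cursor-explicit, `slope` otherwise) without touching `slope`.
#'
#' @param trials A trial tibble.
#' @param run_threshold Passed to [classify_history()].
#' @param strength Add the sign-aligned `strength` column?
#' @param estimates Optional `vp_estimates` used to drop excluded
#'   participants.
#' @return A tibble keyed by (participant, group, kind, preceding_type,
#'   repetition) with `slope`, `intercept`, `n_trials` (and `strength`).
#' @export
sequential_biases <- function(trials, run_threshold = 2L, strength = FALSE,
                              estimates = NULL) {
  long <- trial_deviations(trials)
  hist_cols <- add_history(trials, run_threshold)
  key <- paste(hist_cols$participant, hist_cols$trial_idx)
  idx <- match(paste(long$participant, long$trial_idx), key)
  long$preceding_type <- hist_cols$preceding_type[idx]
  long$repetition <- hist_cols$repetition[idx]
  long <- long[!is.na(long$preceding_type), ]

  grouped <- long |>
    dplyr::group_by(.data$participant, .data$group, .data$kind,
                    .data$preceding_type, .data$repetition)
  sizes <- dplyr::summarise(
    grouped, n_rot = length(unique(.data$rotation_deg)), .groups = "drop"
  )
  n_small <- sum(sizes$n_rot < 3L)
  if (n_small > 0L) {
    warning(n_small, " sequential subset(s) with < 3 distinct rotations ",
            "dropped", call. = FALSE)
  }
  out <- grouped |>
    dplyr::filter(length(unique(.data$rotation_deg)) >= 3L) |>
    dplyr::reframe({
      fit <- fit_bias(.data$deviation, .data$rotation_deg)
      tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                     n_trials = fit$n)
    })
  if (strength) {
    out$strength <- ifelse(out$kind == "cursor-explicit",
                           -out$slope, out$slope)
  }
  if (!is.null(estimates) && "excluded" %in% names(estimates)) {
    drop <- unique(estimates$participant[estimates$excluded])
    out <- out[!out$participant %in% drop, ]
  }
  out
}

#' Sequential-effect ANOVA on subset biases
#'
#' The 2 (group) x 2 (judgment kind) x 2 (preceding type) x 2 (repetition)
#' mixed ANOVA on sequential subset biases, with bias *strength* as the
#' response (cursor-explicit slopes sign-flipped so that larger always
#' means a stronger bias).
#'
#' @param seq_biases A tibble from [sequential_biases()].
#' @param kinds The two judgment kinds to contrast, e.g.
#'   `c("cursor-explicit", "hand-explicit")` or
#'   `c("hand-explicit", "hand-implicit")`.
#' @param gg Greenhouse-Geisser correction; default `FALSE`.
#' @return A `vp_anova`.
#' @export
sequential_anova <- function(seq_biases,
                             kinds = c("cursor-explicit", "hand-explicit"),
                             gg = FALSE) {
  d <- seq_biases[seq_biases$kind %in% kinds, ]
  d$strength <- ifelse(d$kind == "cursor-explicit", -d$slope, d$slope)
  mixed_anova(d, dv = "strength", participant = "participant",
              between = "group",
              within = c("kind", "preceding_type", "repetition"), gg = gg)
}
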