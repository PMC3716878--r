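trial_csv_cols <- c(
  "participant", "group", "trial_idx", "rotation_deg", "judgment_type",
  "target_deg", "hand_deg", "cursor_deg", "judged_deg",
  "t1_x", "t1_y", "end2_x", "end2_y", "end3_x", "end3_y"
)

#' Read and write trial tables as CSV
#'
#' Trial tables are interchanged as plain CSV (UTF-8, header row), one row
#' per trial, all angles in degrees and coordinates in cm. `read_trials()`
#' validates the schema and reports offending rows; `write_trials()` writes
#' the canonical column set plus any generator truth columns present.
#'
#' @param path File path.
#' @return `read_trials()`: a trial tibble; `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            progress = FALSE)
  missing <- setdiff(trial_csv_cols, names(trials))
  if (length(missing) > 0) {
    stop("read_trials(): missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(trial_csv_cols, c("participant", "group",
                                        "judgment_type"))
  for (v in num_cols) {
    if (!is.numeric(trials[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(trials[[v]]))) &
                     !is.na(trials[[v]]))
      stop("read_trials(): non-numeric values in '", v, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad_rot <- which(!trials$rotation_deg %in% rotation_set())
  if (length(bad_rot) > 0) {
    stop("read_trials(): rotation_deg outside the 12-value set at data ",
         "row(s) ", paste(utils::head(bad_rot, 5), collapse = ", "),
         call. = FALSE)
  }
  trials
}

#' @rdname read_trials
#' @param trials A trial tibble.
#' @export
write_trials <- function(trials, path) {
  keep <- intersect(c(trial_csv_cols, "alpha_gen", "outlier_explicit",
                      "outlier_implicit"), names(trials))
  readr::write_csv(trials[, keep], path, progress = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Assembles (or loads from YAML) the settings shared by the pipeline
#' steps.
#'
#' @param seed Non-negative integer master seed.
#' @param presets Named list of [coupling_preset()]s or a YAML preset file
#'   path.
#' @param out_dir Output directory (created if absent).
#' @param screen_trials,screen_participants Screening toggles.
#' @param run_threshold Sequential repetition threshold (run length).
#' @param gg Greenhouse-Geisser correction in the ANOVAs.
#' @return A `vp_config` list.
#' @export
run_config <- function(seed = 1L, presets = default_presets(),
                       out_dir = ".", screen_trials = TRUE,
                       screen_participants = TRUE, run_threshold = 2L,
                       gg = FALSE) {
  if (is.character(presets)) {
    if (!file.exists(presets)) {
      stop("run_config(): preset file not found: ", presets, call. = FALSE)
    }
    presets <- read_presets(presets)
  }
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed), seed >= 0L)
  structure(
    list(seed = seed, presets = presets, out_dir = out_dir,
         screen_trials = screen_trials,
         screen_participants = screen_participants,
         run_threshold = as.integer(run_threshold), gg = gg),
    class = "vp_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML config file with fields `seed`, `presets`
#'   (path or inline list), `out_dir`, `screen_trials`,
#'   `screen_participants`, `run_threshold`, `gg`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$presets) && is.list(raw$presets)) {
    raw$presets <- lapply(raw$presets, function(p) do.call(coupling_preset, p))
  }
  do.call(run_config, raw)
}

out_path <- function(config, name) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  file.path(config$out_dir, name)
}

#' Pipeline step: simulate a cohort to CSV
#'
#' Deterministic for a fixed config seed: simulates the configured cohort
#' and writes `trials.csv` into the output directory.
#'
#' @param config A [run_config()].
#' @return The trial tibble, invisibly; side effect: `trials.csv`.
#' @export
run_simulate <- function(config = run_config()) {
  trials <- simulate_cohort(config$presets, seed = config$seed)
  write_trials(trials, out_path(config, "trials.csv"))
  invisible(trials)
}

#' Pipeline step: estimate biases from a trial CSV
#'
#' Reads (or takes) a trial table, runs screening and per-participant
#' regressions, and writes `estimates.csv` (per participant x judgment
#' kind, with exclusion flags) and `group_summary.csv` (group means and
#' SEs).
#'
#' @param config A [run_config()].
#' @param trials A trial tibble or a CSV path; defaults to `trials.csv` in
#'   the configured output directory.
#' @return The `vp_estimates` tibble, invisibly.
#' @export
run_analyze <- function(config = run_config(),
                        trials = out_path(config, "trials.csv")) {
  if (is.character(trials)) trials <- read_trials(trials)
  est <- analyze_trials(trials, screen_trials = config$screen_trials,
                        screen_participants = config$screen_participants)
  removed <- sum(est$n_removed)
  total <- sum(est$n_used) + removed
  message(sprintf(
    "trial screening removed %d of %d trial judgments (%.2f%%); %d participant(s) excluded",
    removed, total, 100 * removed / total,
    length(unique(est$participant[est$excluded]))
  ))
  readr::write_csv(est, out_path(config, "estimates.csv"), progress = FALSE)
  readr::write_csv(summarize_biases(est),
                   out_path(config, "group_summary.csv"), progress = FALSE)
  invisible(est)
}

#' Pipeline step: the inferential test battery
#'
#' Emits the full set of group-level analyses from a trial table and its
#' estimates: one-sample t-tests of slopes and intercepts against zero
#' (per group and kind, plus intercepts pooled over groups), the
#' 2 (group) x 2 (cursor- vs hand-explicit) bias ANOVA, the 2 x 2
#' (hand-explicit vs hand-implicit) ANOVA, implicit-explicit bias
#' correlations per group, the 2 x 3 x 12 ANOVA on intra-individual SDs,
#' and the two 2 x 2 x 2 x 2 sequential ANOVAs. Results are written as
#' `stats.csv` (one row per effect/test) and returned as a list of
#' tibbles.
#'
#' @param config A [run_config()].
#' @param trials A trial tibble or CSV path.
#' @param estimates A `vp_estimates` tibble or CSV path; recomputed from
#'   `trials` when missing.
#' @return A named list of result tibbles, invisibly.
#' @export
run_report <- function(config = run_config(),
                       trials = out_path(config, "trials.csv"),
                       estimates = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.null(estimates)) {
    estimates <- analyze_trials(trials,
                                screen_trials = config$screen_trials,
                                screen_participants = config$screen_participants)
  } else if (is.character(estimates)) {
    estimates <- readr::read_csv(estimates, show_col_types = FALSE,
                                 progress = FALSE)
  }
  est <- estimates[!estimates$excluded, ]
  if (length(unique(est$group)) < 2L) {
    stop("run_report(): need participants from both groups", call. = FALSE)
  }
  n_per_group <- est |>
    dplyr::distinct(.data$participant, .data$group) |>
    dplyr::count(.data$group)
  if (any(n_per_group$n < 2L)) {
    stop("run_report(): need >= 2 participants per group", call. = FALSE)
  }

  ttests <- est |>
    dplyr::group_by(.data$group, .data$kind) |>
    dplyr::reframe(
      dplyr::bind_rows(
        dplyr::mutate(one_sample_t(.data$slope), parameter = "slope"),
        dplyr::mutate(one_sample_t(.data$intercept), parameter = "intercept")
      )
    )
  ttests_pooled_icpt <- est |>
    dplyr::group_by(.data$kind) |>
    dplyr::reframe(dplyr::mutate(one_sample_t(.data$intercept),
                                 parameter = "intercept_pooled"))

  bias_anova <- mixed_anova(
    est[est$kind %in% c("cursor-explicit", "hand-explicit"), ],
    dv = "slope", participant = "participant", between = "group",
    within = "kind", gg = config$gg
  )
  hand_anova <- mixed_anova(
    est[est$kind %in% c("hand-explicit", "hand-implicit"), ],
    dv = "slope", participant = "participant", between = "group",
    within = "kind", gg = config$gg
  )

  correlations <- bias_correlations(estimates)

  profile <- rotation_profile(trials, estimates)
  sd_anova <- mixed_anova(
    dplyr::mutate(profile, rotation = factor(.data$rotation_deg)),
    dv = "sd_dev", participant = "participant", between = "group",
    within = c("kind", "rotation"), gg = config$gg
  )

  seqb <- sequential_biases(trials, run_threshold = config$run_threshold,
                            estimates = estimates)
  seq_explicit <- sequential_anova(
    seqb, kinds = c("cursor-explicit", "hand-explicit"), gg = config$gg
  )
  seq_hand <- sequential_anova(
    seqb, kinds = c("hand-explicit", "hand-implicit"), gg = config$gg
  )

  results <- list(
    t_tests = dplyr::bind_rows(ttests, ttests_pooled_icpt),
    bias_anova = tidy(bias_anova),
    hand_implicit_anova = tidy(hand_anova),
    correlations = correlations,
    sd_anova = tidy(sd_anova),
    sequential_explicit_anova = tidy(seq_explicit),
    sequential_hand_anova = tidy(seq_hand)
  )
  flat <- purrr::list_rbind(purrr::imap(results, function(tb, nm) {
    dplyr::mutate(tb, analysis = nm, .before = 1)
  }))
  readr::write_csv(flat, out_path(config, "stats.csv"), progress = FALSE)
  invisible(results)
}

#' Pipeline step: variance-reduction curve grid to CSV
#'
#' Writes the [coupling_curves()] grid (bias 0 to 1 in steps of 0.01,
#' variance ratios 0.2 to 0.7) as `curves.csv`.
#'
#' @param config A [run_config()].
#' @return The curve tibble, invisibly.
#' @export
run_curves <- function(config = run_config()) {
  curves <- coupling_curves()
  readr::write_csv(curves, out_path(config, "curves.csv"), progress = FALSE)
  invisible(curves)
}
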