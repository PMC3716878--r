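#' Trial schedule of one session
#'
#' A session crosses the 12 feedback rotations with the two explicit
#' judgment types (hand, cursor), six repetitions each: 144 trials, 72 per
#' judgment type, 12 per rotation, in a seeded uniformly random order.
#'
#' @param seed Integer seed for the permutation.
#' @return A tibble with columns `trial_idx`, `rotation_deg` and
#'   `judgment_type`.
#' @export
make_schedule <- function(seed) {
  withr::local_seed(seed)
  grid <- tidyr::expand_grid(
    rotation_deg = rotation_set(),
    judgment_type = c("hand", "cursor"),
    rep = 1:6
  )
  grid <- grid[sample.int(nrow(grid)), c("rotation_deg", "judgment_type")]
  tibble::tibble(trial_idx = seq_len(nrow(grid)), grid)
}

#' Simulate one participant's session
#'
#' Generates a full 144-trial session from a group preset. Per trial:
#' the target direction is uniform in (-60, 60) deg; the hand direction of
#' the second stroke is `target - rotation` plus motor noise (the
#' participant steers the rotated cursor to the remembered target); the
#' cursor direction is `hand + rotation`. The explicit judged direction of
#' the requested type deviates from the corresponding actual direction by
#' `slope_eff * rotation + intercept + noise`. The implicit deviation is
#' generated for *every* trial (the return stroke precedes the explicit
#' judgment instruction) and is materialized as a stroke-3 endpoint via
#' [make_return_endpoint()], so that [implicit_angular_deviation()] is the
#' exact inverse of the generator up to return-length noise, which leaves
#' the angle untouched.
#'
#' Sequential modulation: the effective slopes depend on the preceding
#' trial's explicit-judgment type and on whether that type was a repetition
#' (see [coupling_preset()]). With probability `outlier_rate` a judged
#' deviation (explicit and implicit independently) is shifted by
#' `outlier_shift` deg with random sign; the truth columns `outlier_explicit`
#' and `outlier_implicit` record these plants.
#'
#' @param preset A [coupling_preset()].
#' @param seed Integer seed for this participant.
#' @param participant Participant identifier (string).
#' @return A tibble of 144 trial records with columns `participant`,
#'   `group`, `trial_idx`, `rotation_deg`, `judgment_type`, `target_deg`,
#'   `hand_deg`, `cursor_deg`, `judged_deg`, `t1_x`, `t1_y`, `end2_x`,
#'   `end2_y`, `end3_x`, `end3_y` plus generator truth columns `alpha_gen`,
#'   `outlier_explicit`, `outlier_implicit`.
#' @export
simulate_participant <- function(preset, seed, participant = "p01") {
  stopifnot(inherits(preset, "vp_preset"))
  sched <- make_schedule(seed)
  withr::local_seed(as.integer((as.numeric(seed) + 1) %% 2147483647))
  n <- nrow(sched)
  rot <- sched$rotation_deg
  type <- sched$judgment_type

  target <- stats::runif(n, -60, 60)
  hand <- wrap_angle(target - rot + stats::rnorm(n, 0, preset$sd_motor))
  cursor <- wrap_angle(hand + rot)

  prev <- c(NA_character_, type[-n])
  prev2 <- c(NA_character_, NA_character_, type[-c(n - 1L, n)])
  repeated <- !is.na(prev) & !is.na(prev2) & prev == prev2
  mult <- ifelse(repeated, preset$repetition_multiplier, 1)

  # explicit judgment of the requested type; delta is a strength increment,
  # so it adds for hand judgments (positive bias) and subtracts for cursor
  # judgments (negative bias)
  is_hand <- type == "hand"
  same <- !is.na(prev) & prev == type
  slope_exp <- ifelse(is_hand, preset$slope_hand_explicit,
                      preset$slope_cursor_explicit) +
    ifelse(same, preset$seq_delta_explicit_same * mult, 0) *
      ifelse(is_hand, 1, -1)
  icpt_exp <- ifelse(is_hand, preset$intercept_hand_explicit,
                     preset$intercept_cursor_explicit)
  sd_exp <- ifelse(is_hand, preset$sd_hand_explicit, preset$sd_cursor_explicit)
  dev_exp <- slope_exp * rot + icpt_exp + stats::rnorm(n, 0, sd_exp)
  outlier_exp <- stats::runif(n) < preset$outlier_rate
  dev_exp <- dev_exp + outlier_exp * sample(c(-1, 1), n, replace = TRUE) *
    preset$outlier_shift
  judged <- wrap_angle(ifelse(is_hand, hand, cursor) + dev_exp)

  # implicit deviation, generated on every trial
  after_hand <- !is.na(prev) & prev == "hand"
  slope_imp <- preset$slope_hand_implicit +
    ifelse(after_hand, preset$seq_delta_implicit_after_hand * mult, 0)
  alpha <- slope_imp * rot + preset$intercept_implicit +
    stats::rnorm(n, 0, preset$sd_implicit)
  outlier_imp <- stats::runif(n) < preset$outlier_rate
  alpha <- alpha + outlier_imp * sample(c(-1, 1), n, replace = TRUE) *
    preset$outlier_shift

  u <- unit_from_angle(hand)
  end2_x <- 15 * u$x
  end2_y <- 15 * u$y
  lambda <- pmax(0.2, stats::rnorm(n, 1, preset$return_length_cv))
  end3 <- make_return_endpoint(0, 0, end2_x, end2_y, alpha, lambda)

  tibble::tibble(
    participant = participant,
    group = preset$group,
    trial_idx = sched$trial_idx,
    rotation_deg = rot,
    judgment_type = type,
    target_deg = target,
    hand_deg = hand,
    cursor_deg = cursor,
    judged_deg = judged,
    t1_x = 0, t1_y = 0,
    end2_x = end2_x, end2_y = end2_y,
    end3_x = end3$x, end3_y = end3$y,
    alpha_gen = alpha,
    outlier_explicit = outlier_exp,
    outlier_implicit = outlier_imp
  )
}

# deterministic, order-independent child seed for participant k of a cohort
child_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 1000003 + 7919 * k) %% 2147483647)
}

#' Simulate a two-group cohort
#'
#' Concatenated sessions for every participant of every preset group
#' (by default 16 young + 19 older, the retained sample sizes of the
#' design). Child seeds are derived deterministically from `seed` with a
#' counter, so each participant's data are independent of the order of
#' simulation and the whole table is reproducible from the one master seed.
#'
#' @param presets Named list of [coupling_preset()]s (one per group), e.g.
#'   [default_presets()].
#' @param seed Integer master seed.
#' @return A tibble of trial records, one row per trial (see
#'   [simulate_participant()]).
#' @examples
#' trials <- simulate_cohort(default_presets(), seed = 1)
#' dplyr::count(trials, group)
#' @export
simulate_cohort <- function(presets = default_presets(), seed = 1L) {
  if (inherits(presets, "vp_preset")) presets <- list(presets)
  k <- 0L
  purrr::list_rbind(purrr::map(presets, function(p) {
    rows <- purrr::map(seq_len(p$n_participants), function(i) {
      id <- sprintf("%s_%02d", p$group, i)
      simulate_participant(p, child_seed(seed, k + i), participant = id)
    })
    k <<- k + p$n_participants
    purrr::list_rbind(rows)
  }))
}
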