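# small, quiet presets for fast exact tests

# fully deterministic generator: no noise, no offsets, no sequential effects
null_preset <- function(group = "young", n = 2L, ...) {
  coupling_preset(
    group = group, n_participants = n,
    slope_hand_explicit = 0, slope_cursor_explicit = 0,
    slope_hand_implicit = 0,
    intercept_hand_explicit = 0, intercept_cursor_explicit = 0,
    intercept_implicit = 0,
    sd_hand_explicit = 0, sd_cursor_explicit = 0, sd_implicit = 0,
    sd_motor = 0, return_length_cv = 0,
    seq_delta_explicit_same = 0, seq_delta_implicit_after_hand = 0,
    repetition_multiplier = 1, outlier_rate = 0, ...
  )
}

# realistic noise but no sequential modulation and no outliers
plain_preset <- function(group = "young", n = 8L, ...) {
  args <- utils::modifyList(
    list(group = group, n_participants = n,
         seq_delta_explicit_same = 0, seq_delta_implicit_after_hand = 0,
         outlier_rate = 0),
    list(...)
  )
  do.call(coupling_preset, args)
}

# per-participant hand-explicit and cursor-explicit slopes via the package
# estimation path, as a named-kind wide tibble
explicit_slopes <- function(trials, screen = TRUE) {
  est <- estimate_biases(trials, screen = screen)
  est[est$kind %in% c("hand-explicit", "cursor-explicit"), ]
}
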