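test_that("fit_bias recovers a noiseless linear relation exactly", {
  rot <- rep(rotation_set(), 6)
  fit <- fit_bias(0.63 * rot + 2, rot)
  expect_equal(fit$slope, 0.63)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$sigma, 0)
  expect_equal(fit_bias(rep(5, length(rot)), rot)$slope, 0)
  expect_error(fit_bias(c(1, 2, 3), c(5, 5, -5)), "3 distinct")
})

test_that("fit_bias agrees with stats::lm", {
  set.seed(21)
  rot <- rep(rotation_set(), 6)
  y <- 0.4 * rot + 1.5 + rnorm(length(rot), 0, 8)
  fit <- fit_bias(y, rot)
  ref <- lm(y ~ rot)
  expect_equal(fit$slope, unname(coef(ref)[2]))
  expect_equal(fit$intercept, unname(coef(ref)[1]))
  expect_equal(fit$sigma, summary(ref)$sigma)
  expect_equal(glance(fit)$n, length(rot))
  expect_equal(tidy(fit)$estimate, unname(coef(ref)[c(1, 2)]))
})

test_that("slope is invariant to a constant shift of all deviations", {
  set.seed(22)
  rot <- rep(rotation_set(), 6)
  y <- 0.3 * rot + rnorm(length(rot), 0, 5)
  f1 <- fit_bias(y, rot)
  f2 <- fit_bias(y + 7.5, rot)
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$intercept, f1$intercept + 7.5)
})

test_that("OLS slope lands within sampling error of the truth", {
  set.seed(23)
  rot <- rep(rotation_set(), 6)
  sxx <- sum((rot - mean(rot))^2)
  reps <- 500
  slopes <- replicate(reps, {
    fit_bias(0.63 * rot + rnorm(length(rot), 0, 12), rot)$slope
  })
  theo_se <- 12 / sqrt(sxx)
  expect_lt(abs(mean(slopes) - 0.63), 3.5 * theo_se / sqrt(reps))
  expect_lt(abs(sd(slopes) - theo_se), 0.2 * theo_se)
})

test_that("trial screening removes a planted gross outlier and only it", {
  set.seed(24)
  rot <- rep(rotation_set(), 6)
  y <- 0.5 * rot + rnorm(length(rot), 0, 2)
  y[40] <- 0.5 * rot[40] + 40
  scr <- screen_trial_outliers(y, rot)
  expect_equal(scr$removed, 40L)

  clean <- 0.5 * rot + rnorm(length(rot), 0, 2)
  expect_lte(length(screen_trial_outliers(clean, rot)$removed), 2L)
})

test_that("screening of noiseless data is a no-op on a degenerate SD", {
  rot <- rep(rotation_set(), 2)
  expect_message(
    scr <- screen_trial_outliers(0.3 * rot, rot),
    "zero residual SD"
  )
  expect_length(scr$removed, 0)
  expect_equal(scr$kept, seq_along(rot))
})

test_that("iterative participant screen excludes a planted extreme bias", {
  set.seed(25)
  x <- c(rnorm(34, 0.6, 0.05), 1.5)
  expect_gt(1.5, mean(x) + 3 * sd(x))  # planted value is outside by construction
  scr <- iterative_outlier_screen(x)
  expect_equal(which(!scr$keep), 35L)
  expect_gte(scr$iterations, 1L)

  same <- rep(0.6, 10)
  scr2 <- iterative_outlier_screen(same)
  expect_true(all(scr2$keep))
  expect_equal(scr2$iterations, 0L)
})

test_that("two-stage screening converges in exactly two iterations", {
  # the 0.8 value becomes an outlier only once the 3.0 value is gone
  x <- c(rep(c(0.59, 0.60, 0.61), length.out = 20), 0.8, 3.0)
  expect_gt(3.0, mean(x) + 3 * sd(x))
  expect_lt(0.8, mean(x) + 3 * sd(x))
  x1 <- x[-22]
  expect_gt(0.8, mean(x1) + 3 * sd(x1))
  scr <- iterative_outlier_screen(x)
  expect_equal(which(!scr$keep), c(21L, 22L))
  expect_equal(scr$iterations, 2L)
  # idempotence at the fixed point
  scr2 <- iterative_outlier_screen(x[scr$keep])
  expect_true(all(scr2$keep))
  expect_equal(scr2$iterations, 0L)
})

test_that("a participant flagged for one kind is excluded everywhere", {
  # n must be large enough that a 3-SD flag is attainable: the largest
  # possible z in a sample of n is (n - 1) / sqrt(n), which only exceeds 3
  # from n = 11 on
  p <- plain_preset(n = 16L)
  tr <- simulate_cohort(list(young = p), seed = 31)
  est <- estimate_biases(tr, screen = FALSE)
  # plant an absurd cursor-explicit slope for one participant
  est$slope[est$participant == "young_03" &
              est$kind == "cursor-explicit"] <- 5
  scr <- screen_participants(est)
  flagged <- scr[scr$participant == "young_03", ]
  expect_true(all(flagged$excluded))
  expect_false(any(scr$excluded[scr$participant != "young_03"]))
})

test_that("estimate accounting: used + removed = available trials per kind", {
  tr <- simulate_cohort(list(young = plain_preset(n = 3L)), seed = 32)
  est <- estimate_biases(tr, screen = TRUE)
  avail <- ifelse(est$kind == "hand-implicit", 144L, 72L)
  expect_equal(est$n_used + est$n_removed, avail)
  est_ns <- estimate_biases(tr, screen = FALSE)
  expect_true(all(est_ns$n_removed == 0L))
})

test_that("clean Gaussian data lose well under 1% of trials to screening", {
  tr <- simulate_cohort(list(young = plain_preset(n = 12L)), seed = 33)
  est <- estimate_biases(tr, screen = TRUE)
  rate <- sum(est$n_removed) / sum(est$n_used + est$n_removed)
  expect_lt(rate, 0.01)
})

test_that("group summaries use closed-form mean and SE", {
  est <- tibble::tibble(
    participant = c("a", "b"), group = "young", kind = "hand-explicit",
    slope = c(0.6, 0.7), intercept = c(1, 3), sigma = 1,
    n_used = 72L, n_removed = 0L
  )
  s <- summarize_biases(est)
  expect_equal(s$slope_mean, 0.65)
  expect_equal(s$slope_se, 0.05)
  expect_equal(s$intercept_mean, 2)
  # degenerate identical cohort: SE 0
  est$slope <- 0.6
  expect_equal(summarize_biases(est)$slope_se, 0)
})

test_that("bias correlations come out near zero for independent biases", {
  tr <- simulate_cohort(default_presets(), seed = 34)
  est <- analyze_trials(tr)
  bc <- bias_correlations(est)
  expect_equal(nrow(bc), 4L)
  expect_true(all(abs(bc$r) <= 1))
  # df = n - 2 per group (16 young, 19 older, minus any screened participant)
  expect_true(all(bc$df >= 12L & bc$df <= 17L))
})
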