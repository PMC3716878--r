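test_that("one-sample t matches hand computation", {
  res <- one_sample_t(c(1, 2, 3))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(one_sample_t(c(-2, -1, 1, 2))$statistic, 0)
  expect_error(one_sample_t(c(5, 5)), "zero variance")
  expect_error(one_sample_t(5), "at least 2")
})

test_that("pearson correlation matches hand computation", {
  expect_equal(pearson_corr(1:4, c(2, 1, 4, 3))$estimate, 0.6)
  expect_equal(pearson_corr(1:5, 2 * (1:5))$estimate, 1)
  # orthogonal constructed vectors
  expect_equal(pearson_corr(c(-1, 1, -1, 1), c(-1, -1, 1, 1))$estimate, 0)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("mixed ANOVA matches a hand-coded sums-of-squares oracle", {
  # 2 groups x 2 within levels, 2 participants per group; the oracle
  # decomposes SS from cell/participant/group means directly
  d <- tidyr::expand_grid(participant = c("p1", "p2", "p3", "p4"),
                          w = c("a", "b"))
  d$group <- rep(c("g1", "g1", "g2", "g2"), each = 2)
  d$y <- c(1, 3, 2, 5, 3, 7, 4, 8)

  gm <- mean(d$y)
  pmean <- tapply(d$y, d$participant, mean)
  gmean <- tapply(d$y, d$group, mean)
  wmean <- tapply(d$y, d$w, mean)
  cmean <- tapply(d$y, list(d$group, d$w), mean)
  ss_between_part <- 2 * sum((pmean - gm)^2)
  ss_group <- 4 * sum((gmean - gm)^2)
  ss_err_b <- ss_between_part - ss_group
  ss_w <- 4 * sum((wmean - gm)^2)
  ss_gw <- 2 * sum((sweep(sweep(cmean, 1, gmean), 2, wmean) + gm)^2)
  ss_total <- sum((d$y - gm)^2)
  ss_err_w <- ss_total - ss_group - ss_err_b - ss_w - ss_gw
  f_group <- (ss_group / 1) / (ss_err_b / 2)
  f_w <- (ss_w / 1) / (ss_err_w / 2)
  f_gw <- (ss_gw / 1) / (ss_err_w / 2)

  tab <- tidy(mixed_anova(d, "y", "participant", "group", "w"))
  expect_equal(tab$statistic[tab$effect == "group"], f_group)
  expect_equal(tab$statistic[tab$effect == "w"], f_w)
  expect_equal(tab$statistic[tab$effect == "group:w"], f_gw)
  expect_equal(tab$df_den[tab$effect == "group"], 2)
  expect_equal(tab$df_den[tab$effect == "w"], 2)
})

test_that("ANOVA effects vanish when all condition means are equal", {
  set.seed(41)
  d <- tidyr::expand_grid(participant = sprintf("p%d", 1:8),
                          w = c("a", "b"))
  d$group <- rep(c("g1", "g2"), each = 4)[match(d$participant,
                                                unique(d$participant))]
  d$y <- rnorm(nrow(d))
  # remove every group x within cell mean: all testable effects are 0
  d <- dplyr::mutate(dplyr::group_by(d, group, w), y = y - mean(y))
  tab <- tidy(mixed_anova(dplyr::ungroup(d), "y", "participant",
                          "group", "w"))
  expect_equal(tab$statistic, rep(0, 3), tolerance = 1e-12)
})

test_that("a 2-level within factor reproduces the paired-t relation F = t^2", {
  set.seed(42)
  d <- tidyr::expand_grid(participant = sprintf("p%d", 1:10),
                          w = c("a", "b"))
  d$y <- rnorm(nrow(d)) + ifelse(d$w == "a", 0.5, 0)
  tab <- tidy(mixed_anova(d, "y", "participant", between = NULL,
                          within = "w"))
  tt <- t.test(d$y[d$w == "a"], d$y[d$w == "b"], paired = TRUE)
  expect_equal(tab$statistic[tab$effect == "w"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(tab$p_value[tab$effect == "w"], tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA power concentrates in the factor carrying the effect", {
  set.seed(43)
  hits <- replicate(60, {
    d <- tidyr::expand_grid(participant = sprintf("p%d", 1:12),
                            w = c("a", "b"))
    idx <- as.integer(factor(d$participant, levels = unique(d$participant)))
    d$group <- ifelse(idx <= 6, "g1", "g2")
    d$y <- rnorm(nrow(d), sd = 0.5) + ifelse(d$group == "g1", 1.5, 0)
    tab <- tidy(mixed_anova(d, "y", "participant", "group", "w"))
    c(group = tab$p_value[tab$effect == "group"] < 0.05,
      w = tab$p_value[tab$effect == "w"] < 0.05)
  })
  expect_gt(mean(hits["group", ]), 0.9)   # pure group effect: high power
  expect_lt(mean(hits["w", ]), 0.25)      # null within effect: near alpha
})

test_that("unbalanced or inconsistent designs are rejected", {
  d <- tidyr::expand_grid(participant = c("p1", "p2", "p3", "p4"),
                          w = c("a", "b"))
  d$group <- rep(c("g1", "g1", "g2", "g2"), each = 2)
  d$y <- rnorm(8)
  expect_error(mixed_anova(d[-1, ], "y", "participant", "group", "w"),
               "balanced")
  d2 <- d
  d2$group[1] <- "g2"  # p1 in two groups
  expect_error(mixed_anova(d2, "y", "participant", "group", "w"),
               "more than one group")
})

test_that("Greenhouse-Geisser epsilon is 1 for two levels, below 1 otherwise", {
  set.seed(44)
  d <- tidyr::expand_grid(participant = sprintf("p%d", 1:10),
                          w = c("a", "b"))
  d$y <- rnorm(nrow(d))
  t1 <- tidy(mixed_anova(d, "y", "participant", between = NULL,
                         within = "w", gg = TRUE))
  expect_equal(t1$epsilon, 1, tolerance = 1e-10)

  d3 <- tidyr::expand_grid(participant = sprintf("p%d", 1:12),
                           w = c("a", "b", "c"))
  d3$y <- rnorm(nrow(d3)) + ifelse(d3$w == "a", rnorm(nrow(d3), sd = 2), 0)
  t3 <- tidy(mixed_anova(d3, "y", "participant", between = NULL,
                         within = "w", gg = TRUE))
  eps <- t3$epsilon[t3$effect == "w"]
  expect_true(eps >= 0.5 && eps <= 1)  # bounded by 1/(k-1) and 1
  t3_raw <- tidy(mixed_anova(d3, "y", "participant", between = NULL,
                             within = "w", gg = FALSE))
  expect_gte(t3$p_value[t3$effect == "w"],
             t3_raw$p_value[t3_raw$effect == "w"])
})

test_that("Bonferroni pairwise tests count comparisons and cap p at 1", {
  set.seed(45)
  d <- tibble::tibble(
    cell = rep(c("a", "b", "c"), each = 10),
    y = c(rnorm(10), rnorm(10), rnorm(10, mean = 5))
  )
  res <- bonferroni_pairwise(d, "y", "cell")
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 3))
  # only the pairs containing the shifted cell are significant
  ab <- res$significant[res$cell_a == "a" & res$cell_b == "b"]
  expect_false(ab)
  expect_true(all(res$significant[res$cell_a == "c" | res$cell_b == "c"]))

  d2 <- tibble::tibble(cell = rep(c("a", "b"), each = 5),
                       y = rep(c(1, 2, 3, 4, 5), 2))
  res2 <- bonferroni_pairwise(d2, "y", "cell")
  expect_false(res2$significant)
  expect_equal(res2$p_adjusted, 1)
})

test_that("paired pairwise tests align participants across cells", {
  set.seed(46)
  base <- rnorm(12, sd = 3)
  d <- tibble::tibble(
    participant = rep(sprintf("p%d", 1:12), 2),
    cell = rep(c("a", "b"), each = 12),
    y = c(base, base + 1 + rnorm(12, sd = 0.2))
  )
  res <- bonferroni_pairwise(d, "y", "cell", participant = "participant")
  expect_equal(res$df, 11)
  expect_true(res$significant)  # paired design sees the within shift
})
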