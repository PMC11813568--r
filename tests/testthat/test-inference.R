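test_that("paired t matches hand-computed statistics", {
  # symmetric differences: t = 0, two-tailed p = 1
  r0 <- paired_t(c(0, 1, 2), c(1, 1, 1), tail = "two")
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  # differences (1,2,3): t = 2 / (1/sqrt(3))
  r1 <- paired_t(c(2, 4, 6), c(1, 2, 3), tail = "one")
  expect_equal(r1$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r1$degrees_of_freedom, 2)
  expect_equal(r1$p_value, 1 - pt(r1$t_statistic, 2), tolerance = 1e-9)
  expect_equal(r1$p_value, 0.03709, tolerance = 1e-4)
  expect_equal(r1$mean_difference, 2)
  # identical vectors: degenerate
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("one-tailed paired p-values test the stated direction", {
  x <- c(2.1, 1.9, 2.5, 2.2); y <- c(1.0, 1.2, 1.4, 0.9)
  expect_lt(paired_t(x, y, tail = "one")$p_value, 0.05)
  # reversed direction: one-tailed p goes to the other tail
  expect_gt(paired_t(y, x, tail = "one")$p_value, 0.95)
})

test_that("Welch t matches the direct formula evaluation", {
  a <- c(0, 1); b <- c(10, 12)
  r <- welch_t(a, b)
  va <- var(a) / 2; vb <- var(b) / 2
  t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_ref <- (va + vb)^2 / (va^2 / 1 + vb^2 / 1)
  expect_equal(r$t_statistic, t_ref, tolerance = 1e-12)
  expect_equal(r$degrees_of_freedom, df_ref, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("Welch reduces to the pooled t for equal n and variance", {
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b) # force equal variance
  r <- welch_t(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$degrees_of_freedom, 18, tolerance = 1e-9)
  expect_equal(r$t_statistic, unname(pooled$statistic), tolerance = 1e-9)
  expect_equal(r$p_value, pooled$p.value, tolerance = 1e-9)
})

test_that("d_av reproduces published-scale effect sizes from summaries", {
  # construct samples with exactly the target means and SDs, then check the
  # effect size equals the summary-statistics formula
  make <- function(m, s, n = 12) {
    x <- rnorm(n); m + (x - mean(x)) / sd(x) * s
  }
  set.seed(9)
  x <- make(1.90, 0.64); y <- make(1.63, 0.85)
  expect_equal(cohen_d_av(x, y), 0.27 / ((0.64 + 0.85) / 2), tolerance = 1e-9)
  expect_equal(round(cohen_d_av(x, y), 2), 0.36)
  x2 <- make(1.92, 0.64, 36); y2 <- make(1.51, 0.79, 36)
  expect_equal(round(cohen_d_av(x2, y2), 2), 0.57)
  # identical distributions: zero effect
  expect_equal(cohen_d_av(x, x), 0)
  # d_z variant: mean over SD of differences
  dz <- cohen_d_av(x, y, variant = "d_z")
  expect_equal(dz, mean(x - y) / sd(x - y), tolerance = 1e-12)
})

test_that("sample-size solver reproduces the a-priori design and is monotone", {
  spec <- required_n_paired_t(0.857, 0.05, 0.80, "one")
  expect_equal(spec$solved_n, 10)
  expect_gte(spec$achieved_power, 0.80)
  # the n below must miss the target power
  expect_lt(power_paired_t(9, 0.857, 0.05, "one"), 0.80)

  # doubling the effect size strictly decreases n
  expect_lt(required_n_paired_t(2 * 0.857, 0.05, 0.80, "one")$solved_n, 10)
  # stricter alpha and higher power need more participants
  expect_gte(required_n_paired_t(0.857, 0.01, 0.80, "one")$solved_n, 10)
  expect_gte(required_n_paired_t(0.857, 0.05, 0.95, "one")$solved_n, 10)
  # two-tailed needs at least as many as one-tailed
  expect_gte(required_n_paired_t(0.857, 0.05, 0.80, "two")$solved_n, 10)
  expect_error(required_n_paired_t(0.857, 0.05, 1), "power")
})

test_that("solver agrees with stats::power.t.test across a grid", {
  for (d in c(0.4, 0.6, 0.857, 1.2)) {
    for (tail in c("one", "two")) {
      alt <- if (tail == "one") "one.sided" else "two.sided"
      ref <- ceiling(power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                  power = 0.8, type = "paired",
                                  alternative = alt)$n)
      got <- required_n_paired_t(d, 0.05, 0.8, tail)$solved_n
      # power.t.test solves a continuous n; the integer solution is its
      # ceiling (or one above when the continuous solution is integral)
      expect_lte(abs(got - ref), 1)
      expect_gte(power_paired_t(got, d, 0.05, tail), 0.8)
    }
  }
})

test_that("floor/ceiling exclusion drops extreme-accuracy participants", {
  tab <- data.frame(
    participant_id = rep(1:3, each = 2),
    condition = rep(c("Cold", "ColdTouch"), 3),
    d_prime = rnorm(6), criterion_C = rnorm(6),
    accuracy = c(0.8, 0.85, 0.97, 0.8, 0.45, 0.8))
  ex <- apply_exclusions(tab)
  expect_setequal(ex$excluded_ids, c(2, 3))
  expect_equal(unique(ex$kept$participant_id), 1)
})

test_that("experiment_summary reports condition stats and planned tests", {
  hy <- cohort_hyperparams(n_participants = 12, gating_mean = 0.55,
                           gating_sd = 0.05, seed = 10)
  tab <- simulate_cohort_sdt(sample_cohort(hy), -1.1,
                             conditions = conditions_all(), seed = 10)
  s <- experiment_summary(tab, experiment = 3)
  expect_equal(s$n, 12)
  expect_setequal(s$condition_stats$condition, conditions_all())
  expect_named(s$comparisons,
               c("d_prime_touch", "C_touch", "d_prime_sound", "C_sound"),
               ignore.order = TRUE)
  expect_equal(s$comparisons$d_prime_touch$tail, "one")
  expect_equal(s$comparisons$C_touch$tail, "two")
  expect_equal(s$comparisons$d_prime_sound$tail, "two")
  # strong gating should surface as a positive Cold-minus-ColdTouch d' gap
  expect_gt(s$comparisons$d_prime_touch$mean_difference, 0)

  # a missing condition for one participant is rejected
  expect_error(experiment_summary(tab[-1, ], experiment = 3),
               "every condition")
})

test_that("gating and sound effects surface in the planned comparisons", {
  # averaged over cohorts, gating lowers ColdTouch d' and a liberal sound
  # shift raises ColdSound C relative to Cold
  dd <- numeric(30); dc <- numeric(30)
  for (r in 1:30) {
    hy <- cohort_hyperparams(n_participants = 12, gating_mean = 0.65,
                             sound_shift_mean = 0.3, seed = 100 + r)
    tab <- simulate_cohort_sdt(sample_cohort(hy), -1.0,
                               conditions = conditions_all(),
                               seed = 200 + r)
    w_d <- reshape(tab[, c("participant_id", "condition", "d_prime")],
                   idvar = "participant_id", timevar = "condition",
                   direction = "wide")
    w_c <- reshape(tab[, c("participant_id", "condition", "criterion_C")],
                   idvar = "participant_id", timevar = "condition",
                   direction = "wide")
    dd[r] <- mean(w_d$d_prime.Cold - w_d$d_prime.ColdTouch)
    dc[r] <- mean(w_c$criterion_C.ColdSound - w_c$criterion_C.Cold)
  }
  expect_gt(mean(dd), 0)
  expect_gt(mean(dc), 0)
  expect_gt(mean(dd > 0), 0.8)
  expect_gt(mean(dc > 0), 0.8)
})

test_that("cross-experiment pooling and Welch comparisons run end to end", {
  tabs <- list()
  for (e in 1:3) {
    hy <- cohort_hyperparams(n_participants = 12, seed = 40 + e)
    conds <- if (e == 3) conditions_all() else c("Cold", "ColdTouch")
    tabs[[as.character(e)]] <-
      simulate_cohort_sdt(sample_cohort(hy), -1.0, conditions = conds,
                          seed = 50 + e)
  }
  cx <- cross_experiment_comparison(tabs)
  expect_equal(cx$pooled_d_prime$n, 36)
  expect_equal(cx$pooled_d_prime$tail, "one")
  expect_equal(cx$pooled_C$tail, "two")
  expect_named(cx$welch, c("d_prime_Cold", "d_prime_ColdTouch",
                           "criterion_C_Cold", "criterion_C_ColdTouch"))
  expect_equal(cx$welch$d_prime_Cold$n1, 24)
  expect_equal(cx$welch$d_prime_Cold$n2, 12)
})
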