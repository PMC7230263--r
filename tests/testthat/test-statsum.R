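test_that("group summaries report mean and SEM with the n-1 denominator", {
  gs <- group_summary(c(0.18, 0.18, 0.18))
  expect_equal(gs$mean, 0.18)
  expect_equal(gs$sem, 0)
  gs2 <- group_summary(c(1, 2, 3))
  expect_equal(gs2$mean, 2)
  expect_equal(gs2$sem, 1 / sqrt(3))   # sd = 1
  expect_warning(gs1 <- group_summary(5), "SEM")
  expect_equal(gs1$sem, 0)
  expect_equal(gs1$mean, 5)
  expect_error(group_summary(numeric(0)), "empty")
  ## SEM shrinks as 1/sqrt(n) on resampled groups
  set.seed(42)
  x <- rnorm(4000)
  s1 <- group_summary(x[1:100])$sem
  s2 <- group_summary(x)$sem
  expect_lt(abs(s2 / s1 - sqrt(100 / 4000)), 0.05)
})

test_that("fold changes reproduce the reported 2.6x and 3.9x ratios", {
  f1 <- fold_change(0.47, 0.18)
  expect_equal(attr(f1, "reported"), 2.6)
  f2 <- fold_change(37788, 9773)
  expect_equal(attr(f2, "reported"), 3.9)
  expect_equal(as.numeric(fold_change(3, 3)), 1)
  expect_error(fold_change(1, 0), "positive")
  ## reciprocity
  expect_equal(as.numeric(fold_change(0.47, 0.18)) *
                 as.numeric(fold_change(0.18, 0.47)), 1)
})

test_that("tumoricidal percentage: 0.18 normalized area is > 80% kill", {
  expect_equal(percent_reduction(0.18), 82)
  expect_gt(percent_reduction(0.18), 80)
  expect_equal(percent_reduction(1), 0)
  expect_equal(percent_reduction(0), 100)
  expect_lt(percent_reduction(1.2), 0)  # net growth
  expect_error(percent_reduction(-0.1), "non-negative")
})

test_that("Welch t and Mann-Whitney match known small-sample answers", {
  ## identical constant groups: p = 1 by convention
  expect_equal(welch_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(welch_t(c(1, 1), c(1, 1))$statistic, 0)
  ## exact U test for {1,2,3} vs {4,5,6}: most extreme of C(6,3) = 20
  ## arrangements on each side -> two-sided p = 2/20 = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.1)
  mwi <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mwi$p_value, 1)
  ## location invariance
  a <- c(0.2, 0.5, 0.4, 0.8); b <- c(1.1, 0.9, 1.4, 1.3)
  expect_equal(welch_t(a, b)$p_value, welch_t(a + 5, b + 5)$p_value)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(a + 5, b + 5)$p_value)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  ## p values in [0, 1]
  expect_gte(welch_t(a, b)$p_value, 0)
  expect_lte(welch_t(a, b)$p_value, 1)
})

test_that("Monte-Carlo Dunnett: no-multiplicity and overwhelming-effect limits", {
  set.seed(7)
  ## two groups only: adjusted p equals the pooled two-sample p within MC error
  g <- list(rnorm(6), rnorm(6, 1))
  ad <- anova_dunnett(g, ndraws = 2e5, seed = 99L)
  tt <- stats::t.test(g[[2]], g[[1]], var.equal = TRUE)
  expect_lt(abs(ad$comparisons$p_adjusted - tt$p.value), 0.01)
  expect_equal(ad$comparisons$p_unadjusted, tt$p.value, tolerance = 1e-9)
  ## adjusted >= unadjusted for every contrast
  g3 <- list(rnorm(5), rnorm(5, 0.5), rnorm(5, 1), rnorm(5))
  ad3 <- anova_dunnett(g3, ndraws = 1e5)
  expect_true(all(ad3$comparisons$p_adjusted >=
                    ad3$comparisons$p_unadjusted - 0.005))
  ## one group shifted by 10 pooled sd: adjusted p < 0.001
  g4 <- list(rnorm(6), rnorm(6), rnorm(6, 10))
  ad4 <- anova_dunnett(g4, ndraws = 1e5)
  expect_lt(ad4$comparisons$p_adjusted[2], 0.001)
  ## rank-based variant runs and keeps p in [0, 1]
  adr <- anova_dunnett(g4, rank = TRUE)
  expect_true(all(adr$comparisons$p_adjusted >= 0 &
                    adr$comparisons$p_adjusted <= 1))
  expect_lt(adr$comparisons$p_adjusted[2], 0.05)
  expect_error(anova_dunnett(list(rnorm(3))), "2")
  expect_error(anova_dunnett(g, control_index = 5), "control")
})

test_that("threshold sensitivity flags stable and unstable size-cutoff sweeps", {
  cutoffs <- seq(500, 3000, by = 500)
  reps <- 1:4
  base <- data.frame(expand.grid(replicate = reps, cutoff = cutoffs))
  base$group <- "static"
  ## identical areas at all cutoffs: p = 1, stable
  base$area <- rep(c(1.0, 1.1, 0.9, 1.05), times = length(cutoffs))
  ts <- threshold_sensitivity(base)
  expect_true(ts$stable)
  expect_equal(ts$per_group$p, 1)
  ## areas dropping sharply above 1000 um^2 (half the area in small
  ## objects): unstable
  drop <- base
  drop$area <- drop$area * ifelse(drop$cutoff > 1000, 0.5, 1)
  ts2 <- threshold_sensitivity(drop)
  expect_false(ts2$stable)
  expect_lt(ts2$per_group$p, 0.05)
  ## unbalanced replicate sets are a usage error
  expect_error(threshold_sensitivity(base[-1, ]), "every cutoff")
})
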