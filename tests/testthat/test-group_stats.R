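test_that("group summary: mean, SEM, degenerate cases", {
  s <- summarize_group(c(1, 2, 3), "x")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))  # sd = 1
  expect_warning(s1 <- summarize_group(5, "one"), "single")
  expect_equal(s1$sem, 0)
  expect_equal(summarize_group(rep(7, 10))$sem, 0)
  expect_error(summarize_group(numeric()), "non-empty")
})

test_that("assumption checks behave on calibrated inputs", {
  set.seed(42)
  g <- list(a = rnorm(200), b = rnorm(200))
  res <- check_assumptions(g)
  ks <- res[res$test == "ks_normality", ]
  expect_true(all(ks$p_value > 0.05))
  lv <- res[res$test == "levene", ]
  expect_gt(lv$p_value, 0.05)

  # gross variance inflation is caught by Levene
  set.seed(7)
  g2 <- list(a = rnorm(30), b = rnorm(30, sd = 10))
  lv2 <- check_assumptions(g2)
  expect_lt(lv2[lv2$test == "levene", "p_value"], 0.01)

  # identical groups: Levene statistic exactly 0
  g3 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  lv3 <- check_assumptions(g3)
  expect_equal(lv3[lv3$test == "levene", "statistic"], 0)

  # small group: normality skipped with flag, not an error
  g4 <- list(a = c(1, 2), b = rnorm(10))
  r4 <- check_assumptions(g4)
  expect_match(r4$flag[r4$groups == "a" & r4$test == "ks_normality"],
               "skipped")
})

test_that("KS normality keeps size under the null and detects gross misses", {
  # the Lilliefors correction should give roughly uniform p under H0
  set.seed(1)
  rej <- mean(vapply(1:200, function(i) {
    lv <- check_assumptions(list(a = rnorm(25), b = rnorm(25)))
    any(lv$p_value[lv$test == "ks_normality"] < 0.05)
  }, TRUE))
  # two tests per replicate at alpha 0.05 -> ~0.10 joint rejection
  expect_lt(rej, 0.2)
  # strongly skewed data is flagged
  set.seed(2)
  r <- check_assumptions(list(a = rexp(100)^2, b = rnorm(100)))
  expect_lt(r$p_value[r$groups == "a" & r$test == "ks_normality"], 0.01)
})

test_that("Dunnett reduces to the pooled t-test for two groups", {
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(8, mean = runif(1, -1, 1))
    r <- anova_dunnett(list(CTL = a, TRT = b), "CTL")
    tt <- stats::t.test(b, a, var.equal = TRUE)
    expect_lt(abs(r$dunnett$p_value - tt$p.value), 1e-6)
  }
})

test_that("Dunnett adjusted p dominates the unadjusted p", {
  set.seed(4)
  for (i in 1:5) {
    g <- list(CTL = rnorm(6), A = rnorm(8, 0.3), B = rnorm(8, 0.8),
              C = rnorm(8, -0.4))
    r <- anova_dunnett(g, "CTL")$dunnett
    expect_true(all(r$p_value >= r$p_unadjusted - 1e-9))
    expect_true(all(r$p_value >= 0 & r$p_value <= 1))
  }
})

test_that("Dunnett is deterministic and validates input", {
  set.seed(5)
  g <- list(CTL = rnorm(6), A = rnorm(8), B = rnorm(8))
  r1 <- anova_dunnett(g, "CTL")
  r2 <- anova_dunnett(g, "CTL")
  expect_identical(r1$dunnett$p_value, r2$dunnett$p_value)
  expect_error(anova_dunnett(g, "XXX"), "not found")
  expect_error(anova_dunnett(list(CTL = rnorm(5)), "CTL"), ">= 2 groups")
  expect_error(anova_dunnett(list(CTL = 1, A = rnorm(4)), "CTL"), "n >= 2")
})

test_that("degenerate all-constant groups are flagged, not fatal", {
  g <- list(CTL = rep(2, 4), A = rep(2, 5), B = rep(2, 3))
  r <- anova_dunnett(g, "CTL")
  expect_match(r$anova$flag, "degenerate")
  expect_equal(r$anova$p_value, 1)
  expect_true(all(r$dunnett$p_value == 1))
})

test_that("unpaired t: closed form, symmetry, degenerate conventions", {
  # textbook two-sample Welch case against the closed form
  a <- c(19.8, 21.2, 20.5, 22.1, 19.9, 20.8)
  b <- c(23.2, 22.8, 24.1, 23.9, 22.5, 24.4)
  r <- unpaired_t(a, b)
  sa <- var(a) / 6; sb <- var(b) / 6
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / 5 + sb^2 / 5)
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(r$statistic, tstat, tolerance = 1e-9)
  expect_equal(r$p_value, p, tolerance = 1e-9)

  r_swap <- unpaired_t(b, a)
  expect_equal(r_swap$p_value, r$p_value, tolerance = 1e-12)
  expect_equal(r_swap$statistic, -r$statistic, tolerance = 1e-12)

  same <- unpaired_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")

  pooled <- unpaired_t(a, b, welch = FALSE)
  expect_equal(pooled$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("significance marks follow the caption conventions", {
  expect_identical(significance_marks(0.03, "vs_control"), "*")
  expect_identical(significance_marks(0.009, "vs_control"), "**")
  expect_identical(significance_marks(0.0009, "vs_control"), "***")
  expect_identical(significance_marks(0.00005, "vs_control"), "****")
  expect_identical(significance_marks(0.00005, "intergroup"), "####")
  expect_identical(significance_marks(0.5, "intergroup"), "")
  expect_identical(significance_marks(0.05, "vs_control"), "")  # strict <
  expect_error(significance_marks(1.2, "vs_control"), "\\[0, 1\\]")
  expect_error(significance_marks(-0.1, "intergroup"), "\\[0, 1\\]")
})

test_that("Dunnett family-wise error is near nominal (reduced replicate check)", {
  # quick null calibration at the study's group sizes; the full 2000-rep
  # version runs in the acceptance suite
  set.seed(11)
  reps <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    g <- list(CTL = rnorm(6), A = rnorm(8), B = rnorm(8), C = rnorm(8))
    if (any(anova_dunnett(g, "CTL")$dunnett$p_value < 0.05)) hits <- hits + 1
  }
  fwer <- hits / reps
  expect_gt(fwer, 0.02)
  expect_lt(fwer, 0.08)
})
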