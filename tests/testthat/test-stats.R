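test_that("one-sample t statistics match hand computation and handle degenerate columns", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = rep(0, 5))
  res <- one_sample_t_fdr(m)
  # mean 3, SD sqrt(2.5): t = 3 / (sqrt(2.5)/sqrt(5))
  expect_equal(res$t[res$level == "a"], 3 / (sqrt(2.5) / sqrt(5)),
               tolerance = 1e-10)
  expect_equal(res$t[res$level == "a"], 4.2426, tolerance = 1e-4)
  expect_equal(res$df[res$level == "a"], 4)
  # a column of exact zeros: no evidence against zero
  zero <- res[res$level == "b", ]
  expect_equal(zero$t, 0)
  expect_equal(zero$p_raw, 1)
  expect_equal(zero$estimate, 0)
  expect_equal(zero$flag, "zero_variance")
  # zero variance with nonzero mean is flagged undefined
  res2 <- one_sample_t_fdr(cbind(a = c(1, 2, 3), b = c(2, 2, 2)))
  expect_true(is.na(res2$t[res2$level == "b"]))
  expect_equal(res2$flag[res2$level == "b"], "zero_variance")
})

test_that("FDR adjustment is Benjamini-Hochberg within the panel", {
  res <- one_sample_t_fdr(matrix(rnorm(40), ncol = 4))
  expect_equal(res$p_fdr, p.adjust(res$p_raw, "BH"))
  expect_true(all(res$p_fdr >= res$p_raw))
  # step-up hand check: p(i) * n / i all equal 0.05
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), "BH"), rep(0.05, 5))
})

test_that("Hedges' g applies the small-sample correction with a normal CI", {
  # n = 9 with mean/SD = 1: J = 1 - 3/31
  x <- c(0, 0, 1, 1, 1, 1, 1, 2, 2)
  expect_equal(mean(x) / sd(x), sqrt(2), tolerance = 1e-10)
  y <- (x - mean(x)) / sd(x) + 1   # rescale to mean/SD exactly 1
  g <- hedges_g(y)
  expect_equal(g$J, 1 - 3 / 31)
  expect_equal(g$g, 1 - 3 / 31)
  expect_lt(abs(g$g), abs(mean(y) / sd(y)))  # |g| < |d| always
  expect_true(g$ci_low < g$g && g$g < g$ci_high)
  expect_equal(g$ci_high - g$g, qnorm(0.975) * sqrt(1 / 9 + g$g^2 / 16),
               tolerance = 1e-10)
  # mean zero: g = 0 with a CI symmetric about 0
  z <- c(-1, 1, -2, 2)
  gz <- hedges_g(z)
  expect_equal(gz$g, 0)
  expect_equal(gz$ci_low, -gz$ci_high)
})

test_that("repeated-measures ANOVA matches the aov oracle on random matrices", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    y <- matrix(rnorm(n * k, mean = rep(rnorm(k), each = n)), n, k)
    ours <- rm_anova(y)
    oracle <- aov_oracle(y)
    expect_equal(ours$ss["effect"], oracle$ss_effect, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(ours$ss["subjects"], oracle$ss_subjects, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(ours$ss["error"], oracle$ss_error, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(ours$F, oracle$F, tolerance = 1e-8)
    expect_equal(ours$p, oracle$p, tolerance = 1e-8)
    expect_true(ours$ges >= 0 && ours$ges <= 1)
  }
})

test_that("ANOVA degrees of freedom and degenerate cases follow the conventions", {
  y <- matrix(rnorm(18 * 3), 18, 3)
  res <- rm_anova(y)
  expect_equal(res$df_effect, 2L)
  expect_equal(res$df_error, 34L)
  # identical columns: no effect
  same <- matrix(rep(rnorm(6), 3), ncol = 3)
  res0 <- rm_anova(same)
  expect_equal(res0$F, 0)
  expect_equal(res0$ges, 0)
  # perfectly additive toy matrix: hand-expanded sums of squares
  toy <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6))
  rt <- rm_anova(toy)
  expect_equal(rt$ss[["effect"]], 8)
  expect_equal(rt$ss[["subjects"]], 15)
  expect_equal(rt$ss[["error"]], 0, tolerance = 1e-12)
  expect_true(is.infinite(rt$F))
  expect_error(rm_anova(cbind(c(1, NA), c(2, 3))), "imputation")
  ph <- rm_anova(y)$posthoc
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_fdr, p.adjust(ph$p_raw, "BH"))
})

test_that("Pearson correlation matches closed forms and flags degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, 2 * x)$r, 1)
  expect_equal(pearson_cor(x, c(1, 3, 2))$r, 0.5)
  set.seed(8)
  big <- rnorm(2000)
  expect_lt(abs(pearson_cor(big, sample(big))$r), 0.08)
  expect_equal(pearson_cor(x, c(2, 2, 2))$flag, "zero_variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("noncentral-F power analysis reproduces the design's sample size", {
  # null effect size: power collapses to alpha exactly
  expect_equal(rm_anova_power(n = 17, f = 0, m = 5), 0.05)
  # power strictly increases with n
  pw <- vapply(3:40, rm_anova_power, numeric(1), f = 0.3, m = 5)
  expect_true(all(diff(pw) > 0))
  # the design target: 17 participants, f = 0.3, five measurements
  expect_gte(rm_anova_power(n = 17, f = 0.3, m = 5), 0.85)
  expect_lt(rm_anova_power(n = 16, f = 0.3, m = 5), 0.85)
  expect_equal(required_n(f = 0.3, m = 5, power = 0.85), 17L)
  # Monte-Carlo noncentral-F oracle for the same configuration
  set.seed(7)
  n <- 17; m <- 5
  df1 <- m - 1; df2 <- (n - 1) * (m - 1)
  lambda <- 0.3^2 * n * m / (1 - 0.5)
  fsim <- (rchisq(2e5, df1, ncp = lambda) / df1) / (rchisq(2e5, df2) / df2)
  power_mc <- mean(fsim > qf(0.95, df1, df2))
  expect_equal(rm_anova_power(n = 17, f = 0.3, m = 5), power_mc,
               tolerance = 0.005)
  expect_error(required_n(f = 0, m = 5), "no finite")
})

test_that("alignment inflates null rejection rates while unaligned tests stay calibrated", {
  # 300 replicate null cohorts of per-salience estimates; the unaligned
  # per-salience one-sample tests reject at ~alpha, the aligned optimal-bin
  # test far above alpha (max-statistic selection bias)
  set.seed(12)
  n <- 15; reps <- 300
  p_unaligned <- numeric(reps); p_aligned <- numeric(reps)
  sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
  for (r in seq_len(reps)) {
    m <- matrix(rnorm(n * 5, 0, 0.1), n, 5)
    p_unaligned[r] <- t.test(m[, 3])$p.value
    eff <- data.frame(participant_id = rep(sprintf("P%02d", 1:n), each = 5),
                      salience_db = rep(sal, n), bl_ip = as.vector(t(m)),
                      op_bl = NA_real_, op_ip = NA_real_)
    a <- suppressWarnings(align_to_optimal(eff))
    p_aligned[r] <- t.test(a$optimal)$p.value
  }
  expect_lt(abs(mean(p_unaligned < 0.05) - 0.05), 0.04)
  expect_gt(mean(p_aligned < 0.05), 0.5)
})
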