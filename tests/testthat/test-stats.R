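test_that("mixed ANOVA matches the brute-force sums-of-squares oracle", {
  # 4 participants x 3 within levels, 2 groups
  mats <- list(OMC = rbind(c(1, 4, 2), c(2, 6, 3)),
               control = rbind(c(5, 5, 5), c(4, 7, 6)))
  d <- long_table(mats)
  a <- mixed_anova(d, "y", "subject", "level", "group")
  o <- split_plot_oracle(d)
  k <- 3; G <- 2; N <- 4
  expect_equal(a$F[a$effect == "group"],
               (o$group / (G - 1)) / (o$subj_err / (N - G)), tolerance = 1e-10)
  expect_equal(a$F[a$effect == "within"],
               (o$time / (k - 1)) / (o$resid / ((N - G) * (k - 1))),
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "interaction"],
               (o$inter / ((G - 1) * (k - 1))) / (o$resid / ((N - G) * (k - 1))),
               tolerance = 1e-10)
  expect_equal(a$eta_p_sq[a$effect == "group"], o$group / (o$group + o$subj_err),
               tolerance = 1e-10)
  expect_equal(a$df1, c(1, 2, 2))
  expect_equal(a$df2, c(2, 4, 4))
  # sums of squares are conserved
  ss <- attr(a, "ss")
  expect_equal(unname(sum(ss[c("group", "subject_error", "within",
                               "interaction", "residual")])),
               unname(ss[["total"]]), tolerance = 1e-9)
})

test_that("mixed ANOVA agrees with aov's split-plot decomposition", {
  set.seed(9)
  # unbalanced group sizes (3 vs 4 subjects), 4 within levels
  mats <- list(OMC = matrix(rnorm(12, 10), 3, 4),
               control = matrix(rnorm(16, 11), 4, 4))
  d <- long_table(mats)
  a <- mixed_anova(d, "y", "subject", "level", "group")
  fit <- stats::aov(y ~ group * level + Error(subject / level), data = d)
  s <- summary(fit)
  tab1 <- s[["Error: subject"]][[1]]
  tab2 <- s[[grep("Within|subject:level", names(s))[1]]][[1]]
  expect_equal(a$F[a$effect == "group"], tab1["group", "F value"], tolerance = 1e-8)
  expect_equal(a$F[a$effect == "within"], tab2["level", "F value"], tolerance = 1e-8)
  expect_equal(a$F[a$effect == "interaction"], tab2["group:level", "F value"],
               tolerance = 1e-8)
  expect_equal(a$p[a$effect == "group"], tab1["group", "Pr(>F)"], tolerance = 1e-8)
})

test_that("identical groups give zero group and interaction F", {
  m <- rbind(c(1, 2, 3), c(4, 6, 5))
  d <- long_table(list(OMC = m, control = m))
  a <- mixed_anova(d, "y", "subject", "level", "group")
  expect_equal(a$F[a$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(a$F[a$effect == "interaction"], 0, tolerance = 1e-12)
  expect_equal(a$eta_p_sq[a$effect == "group"], 0, tolerance = 1e-12)
})

test_that("unbalanced within data and degenerate models raise errors", {
  d <- long_table(list(OMC = rbind(c(1, 2), c(3, 4)),
                       control = rbind(c(5, 6), c(7, 8))))
  expect_error(mixed_anova(d[-1, ], "y", "subject", "level", "group"),
               "unbalanced")
  # a positive within effect with zero residual variance is degenerate
  d0 <- long_table(list(OMC = rbind(c(1, 2), c(1, 2)),
                        control = rbind(c(1, 2), c(1, 2))))
  expect_error(mixed_anova(d0, "y", "subject", "level", "group"), "degenerate")
})

test_that("repeated-measures ANOVA matches its oracle and the paired-t identity", {
  set.seed(10)
  m <- matrix(rnorm(15, 20, 3), 5, 3)
  d <- long_table(list(g = m))
  a <- rm_anova(d, "y", "subject", "level")
  # brute-force: SS_time and SS_resid from subject/level means
  grand <- mean(m)
  ss_time <- 5 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_time - ss_subj
  expect_equal(a$F, (ss_time / 2) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(a$eta_p_sq, ss_time / (ss_time + ss_err), tolerance = 1e-10)
  # two levels: F equals the squared paired t statistic
  m2 <- m[, 1:2]
  a2 <- rm_anova(long_table(list(g = m2)), "y", "subject", "level")
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  # constant scores over the levels: F = 0 by convention
  const <- rm_anova(long_table(list(g = matrix(rep(c(2, 3, 4, 5), 3), 4, 3))),
                    "y", "subject", "level")
  expect_equal(const$F, 0)
})

test_that("Hedges' g: hand example, antisymmetry, shrinkage below Cohen's d", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # pooled SD 1, d = -3, J = 1 - 3/15 = 0.8 -> g = -2.4
  expect_equal(hedges_g(a, b), -2.4, tolerance = 1e-12)
  expect_equal(hedges_g(b, a), 2.4, tolerance = 1e-12)
  expect_equal(hedges_g(a, a), 0)   # equal means
})

test_that("Hedges' g degenerate and magnitude properties", {
  expect_error(hedges_g(c(1, 1), c(1, 1)), "undefined-effect")
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    g <- hedges_g(a, b)
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    d <- (mean(a) - mean(b)) / sp
    expect_lt(abs(g), abs(d) + 1e-12)     # J < 1 shrinks
    expect_equal(sign(g), sign(d))
  }
})

test_that("gated pairwise test picks branches by Shapiro-Wilk and corrects p", {
  set.seed(12)
  a <- rnorm(20, 0); b <- rnorm(20, 3)
  r <- gated_pairwise(a, b, m_comparisons = 4)
  expect_equal(r$test, "t")
  expect_equal(r$p_bonferroni, min(1, 4 * r$p_raw))
  expect_true(is.finite(r$hedges_g))
  # heavily skewed data go non-parametric
  a2 <- exp(rnorm(25, 0, 1.5)); b2 <- exp(rnorm(25, 0.2, 1.5))
  r2 <- gated_pairwise(a2, b2)
  expect_equal(r2$test, "wilcoxon")
  # paired identical samples: t = 0, p = 1
  x <- rnorm(10)
  r3 <- gated_pairwise(x, x, paired = TRUE)
  expect_true(r3$p_raw == 1 || r3$test == "wilcoxon")
})

test_that("Bonferroni correction never drops below raw p and caps at 1", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    m <- sample(1:20, 1)
    r <- gated_pairwise(a, b, m_comparisons = m)
    expect_gte(r$p_bonferroni, r$p_raw)
    expect_lte(r$p_bonferroni, 1)
  }
})
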