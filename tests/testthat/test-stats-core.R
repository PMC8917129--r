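test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # groups (0,1) and (2,3): SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8
  r <- anova_oneway(c(0, 1, 2, 3), c("a", "a", "b", "b"))
  expect_equal(r$statistic, 8)
  expect_equal(r$df, c(1L, 2L))
  # equal means, equal spread: F = 0
  expect_equal(anova_oneway(c(0, 1, 1, 0), c("a", "a", "b", "b"))$statistic, 0)
})

test_that("ANOVA agrees with stats::aov and equals t^2 at k = 2", {
  set.seed(3)
  for (k in 2:4) {
    v <- rnorm(10 * k)
    g <- rep(letters[1:k], each = 10)
    mine <- anova_oneway(v, g)
    ref <- summary(stats::aov(v ~ g))[[1]]
    expect_equal(mine$statistic, ref$`F value`[1])
    expect_equal(mine$p_value, ref$`Pr(>F)`[1])
  }
  v <- rnorm(14); g <- rep(c("x", "y"), each = 7)
  tt <- stats::t.test(v[1:7], v[8:14], var.equal = TRUE)
  expect_equal(anova_oneway(v, g)$statistic, unname(tt$statistic)^2)
})

test_that("ANOVA degenerate and precondition paths", {
  r <- anova_oneway(rep(1, 6), rep(c("a", "b"), 3))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "fewer than")
})

test_that("Tukey HSD at k = 2 equals the pooled t-test p", {
  set.seed(8)
  v <- rnorm(16); g <- rep(c("a", "b"), each = 8)
  ph <- tukey_hsd(v, g)
  tt <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(ph$adjusted_p, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey HSD matches stats::TukeyHSD and flags degenerate input", {
  set.seed(21)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  ph <- tukey_hsd(v, g)
  ref <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
  expect_equal(ph$adjusted_p, unname(ref[, "p adj"]), tolerance = 1e-9)
  expect_equal(ph$estimate, unname(ref[, "diff"]))
  # widely separated balanced groups: all pairwise p < 0.01
  v2 <- c(rnorm(6), rnorm(6) + 10, rnorm(6) + 20)
  g2 <- rep(c("a", "b", "c"), each = 6)
  expect_true(all(tukey_hsd(v2, g2)$adjusted_p < 0.01))
  expect_warning(ph0 <- tukey_hsd(rep(2, 9), rep(c("a", "b", "c"), 3)),
                 "degenerate")
  expect_true(all(ph0$adjusted_p == 1))
})

test_that("Kruskal-Wallis reproduces the rank formula and base R", {
  # {1,2} vs {3,4}: H = 12/20 * (2*1.5^2 + 2*3.5^2) - 15 = 2.4
  expect_equal(kruskal_wallis(1:4, c("a", "a", "b", "b"))$statistic, 2.4)
  set.seed(5)
  v <- round(rnorm(24), 1)  # ties exercise the correction
  g <- rep(c("a", "b", "c"), 8)
  mine <- kruskal_wallis(v, g)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # label permutation leaves H invariant
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(v, c("b", "c", "a")[match(g, c("a", "b", "c"))])$statistic)
  # heavy separation rejects
  v2 <- c(rnorm(5), rnorm(5) + 50)
  expect_lt(kruskal_wallis(v2, rep(c("a", "b"), each = 5))$p_value, 0.05)
  expect_equal(kruskal_wallis(rep(3, 8), rep(c("a", "b"), 4))$p_value, 1)
})

test_that("Dunn test matches a brute-force rank computation", {
  set.seed(13)
  v <- c(rnorm(5), rnorm(5) + 1, rnorm(5) + 3)
  g <- rep(c("a", "b", "c"), each = 5)
  ph <- dunn_test(v, g)
  # independent recomputation from first principles
  r <- rank(v); n <- length(v)
  sigma2 <- n * (n + 1) / 12
  for (row in seq_len(nrow(ph))) {
    ra <- mean(r[g == ph$group_a[row]]); rb <- mean(r[g == ph$group_b[row]])
    z <- (rb - ra) / sqrt(sigma2 * (1 / 5 + 1 / 5))
    expect_equal(ph$raw_p[row], 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
  # k = 2: z^2 equals the tie-corrected H statistic
  v2 <- rnorm(12); g2 <- rep(c("a", "b"), 6)
  z2 <- dunn_test(v2, g2)
  h <- kruskal_wallis(v2, g2)$statistic
  expect_equal(qnorm(z2$raw_p / 2, lower.tail = FALSE)^2, h, tolerance = 1e-9)
  # identical groups: p near 1
  expect_true(all(dunn_test(rep(1:3, 4), rep(c("a", "b"), 6))$raw_p > 0.9))
})

test_that("Wilcoxon exact p comes from full enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  # same multiset: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p_value, 1)
  # agrees with wilcox.test exact on tie-free data
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7) + 0.5
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon normal approximation is close to exact at n = 10", {
  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10) + 0.8
    exact <- wilcoxon_rank_sum(x, y, exact_limit = 20)$p_value
    approx <- wilcoxon_rank_sum(x, y, exact_limit = 0)$p_value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("p-value adjustment reproduces hand computations", {
  expect_equal(adjust_p(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_p(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_p(c(0.01, 0.04, 0.03), "benjamini-hochberg"),
               c(0.03, 0.04, 0.04))
  set.seed(4)
  p <- runif(20)
  expect_true(all(adjust_p(p, "benjamini-hochberg") <=
                    adjust_p(p, "bonferroni") + 1e-12))
  expect_equal(adjust_p(p, "benjamini-hochberg"), stats::p.adjust(p, "BH"))
  expect_error(adjust_p(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("normality routing separates Gaussian from lognormal residuals", {
  set.seed(100)
  expect_identical(normality_route(rnorm(50)), "parametric")
  set.seed(100)
  expect_identical(normality_route(rlnorm(50, sdlog = 1.5)), "nonparametric")
  expect_no_error(normality_route(c(0.1, -0.2, 0.05)))
  expect_warning(r <- normality_route(rep(1, 10)), "constant")
  expect_identical(r, "nonparametric")
})

test_that("permutation p follows the >=-proportion and plus-one rules", {
  expect_equal(permutation_p(5, runif(100)), 0)
  expect_equal(permutation_p(1, rep(1, 50)), 1)
  set.seed(6)
  perm <- rnorm(10000)
  expect_equal(permutation_p(median(perm), perm), 0.5, tolerance = 0.02)
  expect_equal(permutation_p(5, runif(99), rule = "plus-one"), 1 / 100)
})

test_that("rank tests are location invariant and F is shift invariant", {
  set.seed(31)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  for (shift in c(-3, 10)) {
    expect_equal(anova_oneway(v + shift, g)$statistic,
                 anova_oneway(v, g)$statistic, tolerance = 1e-9)
    expect_equal(kruskal_wallis(v + shift, g)$statistic,
                 kruskal_wallis(v, g)$statistic)
  }
})
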