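test_that("identical normal samples give the pooled t with statistic 0, p 1", {
  set.seed(31)
  x <- rnorm(20)
  res <- select_two_sample_test(x, x)
  expect_equal(res$test_name, "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 38)
  expect_true(res$decision_trace$shapiro_x > 0.05)
})

test_that("non-normal samples route to the Wilcoxon rank-sum test", {
  set.seed(32)
  x <- rexp(30); y <- rexp(30)
  # oracle: verify the gate actually fires on this fixture
  expect_lt(shapiro.test(x)$p.value, 0.05)
  res <- select_two_sample_test(x, y)
  expect_equal(res$test_name, "wilcoxon_rank")
  expect_equal(res$p_value,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))$p.value)
})

test_that("normal samples with unequal variances route to Welch", {
  set.seed(33)
  x <- rnorm(30, sd = 1); y <- rnorm(30, sd = 4)
  # oracle: both normal, F-test rejects homogeneity on this fixture
  expect_gt(shapiro.test(x)$p.value, 0.05)
  expect_gt(shapiro.test(y)$p.value, 0.05)
  expect_lt(var.test(x, y)$p.value, 0.05)
  res <- select_two_sample_test(x, y)
  expect_equal(res$test_name, "welch")
  expect_equal(res$p_value, t.test(x, y)$p.value)
  expect_equal(res$decision_trace$f_test, var.test(x, y)$p.value)
})

test_that("pooled t and Welch agree as variances equalize", {
  set.seed(34)
  x <- rnorm(40)
  yb <- rnorm(40)
  gap <- vapply(c(4, 2, 1.2, 1.001), function(s) {
    y <- yb * s
    abs(t.test(x, y, var.equal = TRUE)$statistic - t.test(x, y)$statistic)
  }, numeric(1))
  expect_true(all(diff(gap) <= 1e-12))
  expect_lt(gap[4], 1e-3)
})

test_that("the cascade is deterministic and refuses tiny samples", {
  set.seed(35)
  x <- rnorm(10); y <- rnorm(10)
  r1 <- select_two_sample_test(x, y)
  r2 <- select_two_sample_test(x, y)
  expect_identical(r1, r2)
  expect_error(select_two_sample_test(c(1, 2), y), "at least 3")
})

test_that("paired test selection gates on normality of the differences", {
  # zero-variance differences: degenerate, flagged, p = 1
  res0 <- select_paired_test(rep(0, 10))
  expect_equal(res0$test_name, "degenerate")
  expect_equal(res0$p_value, 1)
  set.seed(36)
  d_norm <- rnorm(25, mean = 0.5)
  expect_gt(shapiro.test(d_norm)$p.value, 0.05)  # oracle on the fixture
  r1 <- select_paired_test(d_norm)
  expect_equal(r1$test_name, "paired_t")
  expect_equal(r1$p_value, t.test(d_norm)$p.value)
  d_heavy <- rcauchy(40)
  expect_lt(shapiro.test(d_heavy)$p.value, 0.05)
  r2 <- select_paired_test(d_heavy)
  expect_equal(r2$test_name, "paired_wilcoxon")
  expect_equal(r2$p_value,
               suppressWarnings(wilcox.test(d_heavy, exact = FALSE,
                                            correct = TRUE))$p.value)
})

test_that("Bonferroni threshold is family_alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
  expect_equal(signif(bonferroni_threshold(0.05, 15), 2), 0.0033)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 4), 0.025)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("chi-square matches the direct sum-over-cells oracle", {
  # demographics table: 29/14 males/females vs 19/6
  res <- chi_square_independence(matrix(c(29, 19, 14, 6), 2))
  expect_equal(round(res$statistic, 2), 0.56)
  expect_equal(res$df, 1)
  expect_equal(round(res$p_value, 2), 0.46)
  # perfectly proportional table -> 0
  expect_equal(chi_square_independence(matrix(c(20, 40, 10, 20), 2))$statistic,
               0)
  # random tables equal the sum((O-E)^2/E) oracle exactly
  set.seed(37)
  for (i in 1:5) {
    o <- matrix(rpois(4, 20) + 1, 2)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(chi_square_independence(o)$statistic, sum((o - e)^2 / e))
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("Spearman correlation uses midranks and flags degenerate input", {
  x <- 10:1
  res <- spearman_lesionload(seq_len(10), x)
  expect_equal(res$statistic, -1)
  # independent samples: small rho, equals the rank-then-Pearson oracle
  set.seed(38)
  a <- rnorm(40); b <- rnorm(40)
  r <- spearman_lesionload(a, b)
  expect_lt(abs(r$statistic), 0.4)
  expect_equal(r$statistic, cor(rank(a), rank(b)))
  # ties: midrank oracle
  a2 <- c(1, 1, 2, 3, 3, 4, 5, 6)
  b2 <- c(2, 1, 2, 3, 5, 4, 4, 7)
  expect_equal(spearman_lesionload(a2, b2)$statistic,
               cor(rank(a2), rank(b2)))
  dg <- spearman_lesionload(rep(1, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(is.na(dg$statistic))
})
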