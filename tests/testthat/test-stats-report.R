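test_that("the U test matches exact enumeration on small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)                      # 2 x 1/20
  expect_equal(res$p_value, mwu_enum_p(c(1, 2, 3), c(10, 11, 12)))
  for (s in 1:3) {
    set.seed(s)
    x <- round(rnorm(5), 3); y <- round(rnorm(6, 0.5), 3)
    expect_equal(mann_whitney_u(x, y)$p_value, mwu_enum_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("the U test behaves at the extremes", {
  expect_gt(mann_whitney_u(c(1, 2, 3, 4), c(1.01, 2.01, 3.01, 4.01))$p_value,
            0.6)
  set.seed(4)
  expect_lt(mann_whitney_u(rnorm(60), rnorm(60, 2))$p_value, 0.001)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("the signed-rank test is exact for small n, including ties", {
  res <- wilcoxon_signed_rank(1:6, 1:6 + 1)
  expect_equal(res$p_value, 2 / 64)                    # all-positive, n = 6
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)
  d <- c(0.3, -0.1, 0.7, 0.2, 0.5, -0.4, 0.6, 0.15)
  ours <- wilcoxon_signed_rank(rep(0, 8), d)$p_value
  ref <- wilcox.test(d, exact = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("exact and large-sample signed-rank p converge", {
  set.seed(11)
  d <- rnorm(12, 0.4)
  p_exact <- wilcoxon_signed_rank(rep(0, 12), d)$p_value
  p_norm <- suppressWarnings(wilcox.test(d, exact = FALSE,
                                         correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_norm), 0.02)
})

test_that("the printed 2x2 neuron-count comparison reproduces", {
  tab <- matrix(c(17, 7, 47, 75), 2)   # LRD+ / LRD- by interneuron / PC
  res <- chi2_2x2(tab)
  expect_equal(res$statistic, 8.51, tolerance = 0.01)
  expect_equal(round(res$p_value, 4), 0.0035)
})

test_that("chi-square matches the closed form and handles degeneracy", {
  for (s in 1:4) {
    set.seed(s)
    t <- matrix(rpois(4, 20) + 1, 2)
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    n <- sum(t)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi2_2x2(t)$statistic, closed, tolerance = 1e-10)
  }
  eq <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi2_2x2(eq)$statistic, 0)
  expect_equal(chi2_2x2(eq)$p_value, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("the paired t test matches the closed form and flags degeneracy", {
  pre <- c(1, 2, 3); post <- c(2, 2.5, 4.5)
  d <- post - pre
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  res <- paired_t(pre, post)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(abs(t_manual), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(paired_t(1:5, 1:5 + 2), "zero variance")
})

test_that("rank tests hold their nominal type-I error on the null", {
  set.seed(21)
  reps <- 600
  rej <- replicate(reps, {
    x <- rnorm(15); y <- rnorm(15)
    c(mann_whitney_u(x, y)$p_value < 0.05,
      paired_t(x, y)$p_value < 0.05)
  })
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej[1, ]) - 0.05), 3 * se + 0.01)
  expect_lt(abs(mean(rej[2, ]) - 0.05), 3 * se + 0.01)
})

test_that("summaries follow the n >= 10 box / n < 10 bar rule", {
  b <- summarize_values(1:11)
  expect_equal(b$type, "box")
  expect_equal(b$median, 6)
  expect_equal(b$q1, quantile(1:11, 0.25, names = FALSE))
  expect_equal(length(b$outliers), 0L)

  s <- summarize_values(c(1, 2, 3, 4, 100))
  expect_equal(s$type, "bar")
  expect_equal(s$mean, 22)
  expect_equal(s$sd, sd(c(1, 2, 3, 4, 100)))

  out <- summarize_values(c(1:11, 100))
  expect_true(100 %in% out$outliers)
  expect_lt(out$whisker_high, 100)
})
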