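test_that("KS normality screen behaves on null, skewed and degenerate data", {
  withr::with_seed(40, {
    expect_gt(ks_normality(rnorm(200)), 0.05)
    expect_lt(ks_normality(rexp(100)), 0.05)
  })
  expect_error(ks_normality(rep(3, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "n >= 3")
})

test_that("signed-rank test: identities, closed forms, enumeration oracle", {
  x <- c(1.2, 5.3, 0.7, 9.1)
  expect_equal(wilcoxon_signed_rank(x, x)$p_value, 1)

  # n = 6, all differences positive: two-sided exact p = 2/64
  pre <- rep(0, 6)
  post <- c(1.1, 2.3, 0.4, 3.2, 5.5, 0.9)
  w <- wilcoxon_signed_rank(pre, post)
  expect_equal(w$statistic, 21)
  expect_equal(w$p_value, 2 / 64)

  # exact p matches full 2^n enumeration for n <= 12
  withr::with_seed(41, {
    for (rep in 1:15) {
      n <- sample(5:12, 1)
      d <- round(rnorm(n), 6)
      w <- wilcoxon_signed_rank(rep(0, n), d)
      expect_equal(w$p_value, wilcoxon_enum_oracle(d), tolerance = 1e-12)
    }
  })

  # exact vs normal approximation agree closely at n = 25
  withr::with_seed(42, {
    d <- rnorm(25)
    exact <- wilcoxon_signed_rank(rep(0, 25), d)$p_value
    approx <- wilcoxon_signed_rank(rep(0, 25), d, exact_max = 0)$p_value
    expect_lt(abs(exact - approx), 0.01)
  })

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "unequal")
})

test_that("Cliff's delta: closed cases, oracle, invariances", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(1, 2), c(5, 6)), -1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 2, 4)), cliffs_oracle(c(1, 2, 3), c(2, 2, 4)))
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 2, 4)), -1 / 3)
  withr::with_seed(43, {
    for (rep in 1:10) {
      x <- rnorm(8); y <- rnorm(11)
      expect_equal(cliffs_delta(x, y), cliffs_oracle(x, y))
      expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))
      expect_equal(cliffs_delta(exp(x), exp(y)), cliffs_delta(x, y))
    }
  })
  expect_error(cliffs_delta(numeric(0), 1), "empty")
})

test_that("BH adjustment matches hand computation and its properties", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(44, {
    for (rep in 1:10) {
      p <- runif(sample(2:12, 1))
      adj <- fdr_adjust(p)
      expect_equal(adj, p.adjust(p, "BH"))   # independent implementation
      expect_true(all(adj >= p - 1e-12))
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-12))
    }
  })
})

test_that("cohort comparison: complete cases, formatting, sign convention", {
  metrics <- data.frame(
    subject = sprintf("S%02d", 1:8),
    burden_pre = c(10, 8, 6, 12, 9, 7, 11, 5),
    burden_post = c(2, 3, 1, 4, 2, 6, 3, NA),
    spindle_fast_pre = c(0.5, 0.8, 0.6, 1.0, 0.7, 0.9, 0.4, 0.8),
    spindle_fast_post = c(1.5, 1.2, 1.6, 2.0, 1.1, 1.9, 1.4, 1.8))
  res <- compare_cohort(metrics, c("burden", "spindle_fast"))
  expect_s3_class(res, "paired_cohort_result")
  expect_equal(res$n, c(7, 8))
  expect_equal(res$n_excluded, c(1, 0))
  expect_lt(res$cliffs_delta[1], 0)      # decrease -> negative delta
  expect_gt(res$cliffs_delta[2], 0)      # increase -> positive delta
  expect_true(all(res$fdr_adjusted_p >= res$p_value - 1e-12))
  expect_match(res$pre[1], "^\\d+\\.\\d+ \\[\\d")   # "median [range]" style
  expect_error(compare_cohort(metrics, "gamma"), "gamma")

  sub <- compare_subgroups(c(1, 2, 3, 10, 11, 12),
                           c("a", "a", "a", "b", "b", "b"))
  expect_equal(sub$cliffs_delta, -1)
  expect_lt(sub$p_value, 0.2)
  expect_error(compare_subgroups(1:4, rep("a", 4)), "two levels")
})
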