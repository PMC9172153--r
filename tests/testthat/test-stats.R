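# Statistical kernel: Welch's t-test, Spearman correlation and the
# signed normalized contrast.

test_that("welch_t reproduces hand-computed and oracle values", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.6742, tolerance = 1e-4)
  expect_equal(w$df, 4.0, tolerance = 1e-9)
  expect_equal(w$p, 0.02131, tolerance = 1e-4)

  # published serum-chemistry summary: 43.9 (SD 7.1, n=6) vs 23.0 (SD 9.3, n=6)
  s <- welch_t_from_summary(43.9, 7.1, 6, 23.0, 9.3, 6)
  expect_equal(s$t, 4.3754, tolerance = 1e-4)
  expect_equal(s$p, 0.001628, tolerance = 1e-3)
  expect_lt(s$p, 0.04)

  # equal-variance groups: Welch df equals the pooled df
  w2 <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_equal(w2$df, 4)
})

test_that("welch_t matches stats::t.test on random instances", {
  set.seed(42)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    w <- welch_t(a, b)
    o <- t.test(a, b)
    expect_equal(w$t, unname(o$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(o$parameter), tolerance = 1e-10)
    expect_equal(w$p, o$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t handles degenerate zero-variance groups deterministically", {
  w <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_false(w$degenerate)

  w2 <- welch_t(c(5, 5, 5), c(7, 7, 7))
  expect_equal(w2$p, 0)
  expect_true(w2$degenerate)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t_from_summary(1, 0, 1, 2, 1, 3), "n >= 2")
})

test_that("welch_t is antisymmetric in its arguments", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(5)
    w1 <- welch_t(a, b); w2 <- welch_t(b, a)
    expect_equal(w1$t, -w2$t)
    expect_equal(w1$p, w2$p)
  }
})

test_that("welch_t at 3 vs 3 is conservative at the nominal level", {
  # the design rationale for skipping FDR downstream: on null data the
  # small-sample Welch test rejects at no more than the nominal rate
  set.seed(11)
  p <- replicate(10000, welch_t(rnorm(3), rnorm(3))$p)
  frac <- mean(p < 0.05)
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 10000))
  expect_gt(frac, 0.01)
  # agreement with the reference implementation under identical draws
  set.seed(11)
  p_ref <- replicate(10000, t.test(rnorm(3), rnorm(3))$p.value)
  expect_equal(p, p_ref, tolerance = 1e-12)
})

test_that("spearman_rho matches rank arithmetic and known values", {
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  xs <- c(0.5, 1, 2, 3.5, 7)
  expect_equal(spearman_rho(xs, xs^2), 1)            # monotone transform
  expect_equal(spearman_rho(xs, -xs^3), -1)
  set.seed(5)
  for (i in 1:50) {
    x <- sample(20, 8, replace = TRUE)               # ties included
    y <- rnorm(8)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), -spearman_rho(x, -y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_warning(out <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out))
})

test_that("spearman_rho is invariant under strictly increasing transforms", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, rank(y)), spearman_rho(x, y))
  }
})

test_that("spearman_critical follows the t-approximation", {
  expect_equal(spearman_critical(571, 0.05, "one"), 0.0689, tolerance = 1e-3)
  expect_equal(spearman_critical(5, 0.05, "two"), 0.8783, tolerance = 1e-3)
  expect_lt(spearman_critical(571, 0.999, "one"), 0.001)  # alpha -> 1 limit
  # monotone in n and alpha
  expect_lt(spearman_critical(1000, 0.05, "one"),
            spearman_critical(100, 0.05, "one"))
  expect_lt(spearman_critical(100, 0.10, "one"),
            spearman_critical(100, 0.01, "one"))
  expect_error(spearman_critical(100, 1.5), "alpha")
  expect_error(spearman_critical(3, 0.05), "n >= 4")
})

test_that("normalized_contrast has the documented edge and symmetry behaviour", {
  expect_equal(normalized_contrast(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(normalized_contrast(c(1, 1, 1), c(0, 0, 0)), 1)   # right edge
  expect_equal(normalized_contrast(c(0, 0), c(0.3, 0.5)), -1)    # left edge
  expect_equal(normalized_contrast(0.25, 0.75), -0.5)
  expect_true(is.na(normalized_contrast(c(0, 0), c(0, 0))))
  expect_error(normalized_contrast(c(-1, 0), c(1, 1)), "non-negative")
})

test_that("normalized_contrast is scale-invariant and bounded", {
  set.seed(3)
  for (i in 1:50) {
    a <- runif(3, 0, 5); b <- runif(3, 0, 5); k <- runif(1, 0.01, 100)
    x <- normalized_contrast(a, b)
    expect_equal(normalized_contrast(k * a, k * b), x, tolerance = 1e-12)
    expect_lte(abs(x), 1)
  }
})
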