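test_that("pearson_r matches exact and hand-computed cases", {
  expect_equal(pearson_r(sample_dataset(1:10, 2 * (1:10) + 1)), 1)
  expect_equal(pearson_r(sample_dataset(1:10, -(1:10))), -1)
  # frozen definitional-formula oracle, computed independently pre-build
  d <- sample_dataset(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5))
  expect_equal(pearson_r(d), 0.8285714285714286, tolerance = 1e-12)
})

test_that("zero-variance input is an undefined-correlation error", {
  d <- sample_dataset(c(1, 2, 3, 4), c(5, 6, 7, 8))
  d$y <- rep(1, 4)  # bypass constructor to hit the computation guard
  expect_error(pearson_r(d), "zero variance")
})

test_that("the t-test matches the frozen t-distribution oracle and cor.test", {
  # frozen oracle (scipy, pre-build): r = 0.45, n = 30
  d <- sample_bivariate(30, 0.45, seed = 4)
  # exact algebraic case first
  res <- correlation_test(d)
  expect_equal(res$df, 28L)
  expect_equal(res$t_stat,
               res$r_hat * sqrt(28) / sqrt(1 - res$r_hat^2))
  # frozen numbers for r exactly 0.45
  tp <- corcompat:::.cor_test_core(0.45, 30)
  expect_equal(unname(tp["t"]), 2.6664054208500554, tolerance = 1e-12)
  expect_equal(unname(tp["p"]), 0.012591071275196772, tolerance = 1e-12)
  # independent cross-check of the full path against stats::cor.test
  for (seed in 1:5) {
    d <- sample_bivariate(25, 0.3, seed = seed)
    mine <- correlation_test(d)
    ref <- stats::cor.test(d$x, d$y)
    expect_equal(mine$r_hat, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("test edge cases: zero correlation, perfect correlation, strictness", {
  # construct r = 0 exactly: x symmetric, y orthogonal to centred x
  x <- c(-2, -1, 1, 2); y <- c(1, -1, -1, 1)
  expect_equal(pearson_r(sample_dataset(x, y)), 0)
  res <- correlation_test(sample_dataset(x, y))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  # |r| = 1: p = 0, degenerate flag, no error
  res1 <- correlation_test(sample_dataset(1:6, 3 * (1:6)))
  expect_equal(res1$p_value, 0)
  expect_true(res1$degenerate)
  expect_true(res1$significant)
  # strict inequality at the threshold: p == alpha is not significant
  res2 <- correlation_test(sample_bivariate(30, 0.45, seed = 4), alpha = 1 - 1e-12)
  expect_true(res2$significant)
  tp <- corcompat:::.cor_test_core(0, 10)
  expect_false(unname(tp["p"]) < 1)  # p = 1 at r = 0
})

test_that("p-values are uniform under the null (KS check)", {
  set.seed(21)
  p <- vapply(1:2000, function(i) {
    d <- sample_bivariate(15, 0, seed = 200000 + i)
    correlation_test(d)$p_value
  }, numeric(1))
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("p-value is invariant to affine rescaling and decreasing in n", {
  d <- sample_bivariate(40, 0.3, seed = 31)
  d2 <- sample_dataset(5 * d$x - 2, -0.1 * d$y + 7)
  expect_equal(correlation_test(d2)$p_value, correlation_test(d)$p_value,
               tolerance = 1e-12)
  p_of_n <- vapply(c(10, 20, 40, 80, 160), function(n)
    unname(corcompat:::.cor_test_core(0.3, n)["p"]), numeric(1))
  expect_true(all(diff(p_of_n) < 0))
})

test_that("fisher_interval matches the closed-form oracle and is well-behaved", {
  # frozen oracle (pre-build): tanh(atanh(0.45) +/- 1.959964/sqrt(27))
  iv <- fisher_interval(0.45, 30, 0.95)
  expect_equal(iv$lower, 0.10709278247377603, tolerance = 1e-12)
  expect_equal(iv$upper, 0.69723300576572980, tolerance = 1e-12)
  # symmetry at r = 0
  iv0 <- fisher_interval(0, 30, 0.9)
  expect_equal(iv0$lower, -iv0$upper, tolerance = 1e-12)
  # width strictly decreasing in n, increasing in level
  w <- function(n, lv) { i <- fisher_interval(0.4, n, lv); i$upper - i$lower }
  expect_true(all(diff(vapply(c(10, 30, 100, 300), w, numeric(1), lv = 0.95)) < 0))
  expect_true(all(diff(vapply(c(0.5, 0.8, 0.95, 0.99), function(l) w(30, l),
                              numeric(1))) > 0))
  expect_error(fisher_interval(1, 30), "r_hat")
})

test_that("95% Fisher interval coverage is close to nominal", {
  set.seed(17)
  covered <- 0L
  R <- 4000
  for (i in 1:R) {
    d <- sample_bivariate(30, 0.45, seed = 300000 + i)
    iv <- fisher_interval(pearson_r(d), 30, 0.95)
    if (iv$lower <= 0.45 && 0.45 <= iv$upper) covered <- covered + 1L
  }
  expect_lt(abs(covered / R - 0.95), 0.015)
})

test_that("interval-test equivalence is exact on the z scale, approximate on t", {
  # z-based: the 95% Fisher interval excludes 0 iff the Fisher-z test of
  # rho = 0 rejects at 0.05 -- exact by construction, for every sample
  set.seed(23)
  mismatch_z <- 0L; mismatch_t <- 0L
  for (i in 1:400) {
    d <- sample_bivariate(8, 0.35, seed = 400000 + i)
    r <- pearson_r(d)
    iv <- fisher_interval(r, d$n, 0.95)
    excl0 <- iv$lower > 0 || iv$upper < 0
    p_z <- 2 * stats::pnorm(sqrt(d$n - 3) * abs(atanh(r)), lower.tail = FALSE)
    p_t <- correlation_test(d)$p_value
    if (excl0 != (p_z < 0.05)) mismatch_z <- mismatch_z + 1L
    if (excl0 != (p_t < 0.05)) mismatch_t <- mismatch_t + 1L
  }
  expect_identical(mismatch_z, 0L)
  # the t-test disagrees with the z interval for a nonzero share of
  # small-n samples: the equivalence is approximate, not exact
  expect_gt(mismatch_t, 0L)
})

test_that("analytic Fisher-z power behaves correctly", {
  expect_equal(power_fisher_z(0, 30), 0.05, tolerance = 1e-10)
  expect_true(all(diff(vapply(seq(10, 100, 10), power_fisher_z, numeric(1),
                              rho = 0.3)) > 0))
  expect_equal(power_fisher_z(0.45, 20), power_fisher_z(-0.45, 20))
})
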