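test_that("a perfectly separated outcome yields estimate 1 and tiny p", {
  g <- rep(c("LL", "MEL"), each = 20)
  y <- as.numeric(g == "MEL") + rnorm(40, 0, 1e-8)
  r <- adjusted_group_comparison(y, g, transform = "identity")
  expect_equal(r$estimate, 1, tolerance = 1e-5)
  expect_lt(r$p, 1e-30)
  expect_identical(r$evidence, "strong")
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("transform registry is applied and recorded", {
  set.seed(51)
  g <- rep(c("LL", "MEL"), each = 50)
  y_skew <- exp(rnorm(100))
  expect_identical(adjusted_group_comparison(y_skew, g)$transform, "log")
  y_sym <- rnorm(100)
  expect_identical(adjusted_group_comparison(y_sym, g)$transform, "identity")
  y_neg_skew <- -exp(rnorm(100))
  expect_identical(adjusted_group_comparison(y_neg_skew, g)$transform,
                   "rank_normal")
  expect_error(adjusted_group_comparison(y_sym, g, transform = "bogus"),
               "registry")
})

test_that("degenerate designs raise informative errors", {
  g <- rep(c("LL", "MEL"), each = 10)
  expect_error(adjusted_group_comparison(rep(1, 20), g), "constant")
  covs <- data.frame(a = as.numeric(g == "MEL"))  # collinear with group
  expect_error(adjusted_group_comparison(rnorm(20), g, covs,
                                         transform = "identity"),
               "collinear|singular")
  expect_error(adjusted_group_comparison(rnorm(20), rep("LL", 20)),
               "two levels")
})

test_that("covariate adjustment removes confounded group differences", {
  # outcome depends only on BMI; groups differ in BMI
  set.seed(52)
  ps_adj <- replicate(40, {
    g <- rep(c("LL", "MEL"), each = 50)
    bmi <- rnorm(100, ifelse(g == "MEL", 29, 25), 2)
    y <- exp(0.08 * bmi + rnorm(100, 0, 0.3))
    adjusted_group_comparison(y, g, data.frame(bmi = bmi),
                              transform = "log")$p
  })
  expect_gt(stats::ks.test(ps_adj, "punif")$p.value, 0.01)
})

test_that("Cohen's d and the noncentral-t sample sizes", {
  expect_equal(cohens_d(0, 2), 0)
  expect_equal(cohens_d(1, 1), 1)
  expect_equal(cohens_d(0.58, 1), 0.58)
  expect_error(cohens_d(1, 0), "positive")

  expect_equal(as.integer(sample_size_two_sample_t(0.62)), 84L)
  expect_equal(as.integer(sample_size_two_sample_t(0.70)), 68L)
  expect_equal(as.integer(sample_size_two_sample_t(0.78)), 54L)

  # independent cross-check against stats::power.t.test
  for (d in c(0.3, 0.5, 0.9)) {
    n <- attr(sample_size_two_sample_t(d), "n_per_group")
    expect_equal(n, ceiling(stats::power.t.test(delta = d, power = 0.8,
                                                sig.level = 0.05)$n))
  }
  # minimal-n contract: one subject fewer misses the target power
  n42 <- attr(sample_size_two_sample_t(0.62), "n_per_group")
  expect_gte(attr(sample_size_two_sample_t(0.62), "achieved_power"), 0.8)
  expect_lt(fdgclamp:::.t_power(n42 - 1L, 0.62, 0.05), 0.8)

  # monotonicity in d and power
  ns <- sapply(c(0.4, 0.6, 0.8, 1.0), sample_size_two_sample_t)
  expect_true(all(diff(ns) < 0))
  np <- sapply(c(0.7, 0.8, 0.9), function(pw)
    sample_size_two_sample_t(0.6, power = pw))
  expect_true(all(diff(np) > 0))
  expect_error(sample_size_two_sample_t(-1), "positive")
  expect_error(sample_size_two_sample_t(0.5, power = 1.2), "power")
})
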