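# enumeration oracles, independent of the implementations under test ------

# exact two-sided rank-sum p by enumerating all group assignments
ranksum_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combs <- utils::combn(length(pooled), length(a))
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- length(a) * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
signrank_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

test_that("annualized deltas divide the change by the follow-up interval", {
  expect_equal(annualized_delta(1, 3, 2), 1)
  expect_equal(annualized_delta(5, 5, 3.7), 0)
  expect_equal(annualized_delta(0.5, 0.4, 0.83), -0.1 / 0.83)
  expect_equal(annualized_delta(c(1, 2), c(2, 6), c(1, 2)), c(1, 2))
  expect_error(annualized_delta(1, NA, 1), "missing")
})

test_that("rank-sum p-values match the enumeration oracle", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- group_compare(a, b)
  expect_equal(res$p_value, 0.1)                       # 2 / choose(6, 3)
  expect_equal(res$p_value, ranksum_enum_p(a, b))
  set.seed(42)
  x <- rnorm(7); y <- rnorm(6) + 0.8
  expect_equal(group_compare(x, y)$p_value, ranksum_enum_p(x, y),
               tolerance = 1e-12)
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("signed-rank p-values match the enumeration oracle", {
  d10 <- 1:10
  res <- paired_change_test(d10)
  expect_equal(res$p_value, 2 / 1024)
  expect_equal(res$p_value, signrank_enum_p(d10))
  set.seed(7)
  d <- rnorm(9, 0.4)
  expect_equal(paired_change_test(d)$p_value, signrank_enum_p(d),
               tolerance = 1e-12)
  sym <- c(-2, 2, -1, 1)
  expect_equal(paired_change_test(sym)$p_value, 1)
  expect_equal(paired_change_test(c(0, 0, 5))$p_value, 1)  # single nonzero
  expect_error(paired_change_test(c(0, 0)), "zero")
})

test_that("zeros are dropped before the signed-rank test", {
  d <- c(0, 0, 1, 2, 3)
  expect_identical(paired_change_test(d)$n, 3L)
})

test_that("Spearman rho hits the closed form and its exact permutation p", {
  x <- 1:10
  expect_equal(rank_correlation(x, x)$statistic, 1)
  expect_equal(rank_correlation(x, -x)$statistic, -1)
  # no-tie closed form 1 - 6 sum d^2 / (n (n^2 - 1)) as an oracle
  set.seed(3)
  y <- rnorm(8)
  xs <- rnorm(8)
  dd <- rank(xs) - rank(y)
  rho_formula <- 1 - 6 * sum(dd^2) / (8 * 63)
  res <- rank_correlation(xs, y)
  expect_equal(res$statistic, rho_formula, tolerance = 1e-12)
  # exact permutation p agrees with the exact distribution in cor.test
  ct <- suppressWarnings(cor.test(xs, y, method = "spearman"))
  expect_equal(res$p_value, ct$p.value, tolerance = 0.005)
  expect_error(rank_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("rank correlation is invariant to strictly monotone transforms", {
  set.seed(11)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- rank_correlation(x, y, n_perm = 2000, seed = 5L)
  r1 <- rank_correlation(exp(x), y, n_perm = 2000, seed = 5L)
  r2 <- rank_correlation(x, y^3 + 10 * y, n_perm = 2000, seed = 5L)
  expect_equal(r1$statistic, r0$statistic)
  expect_equal(r2$statistic, r0$statistic)
  expect_equal(r1$p_value, r0$p_value)
})

test_that("linear fit recovers exact lines and matches normal equations", {
  x <- c(0, 1, 2, 3)
  res <- linear_fit(x, 2 * x + 1)
  expect_equal(unname(res$effect["slope"]), 2)
  expect_equal(unname(res$effect["intercept"]), 1)
  expect_equal(unname(res$effect["r_squared"]), 1)
  # hand-computable 4-point set via normal equations
  y <- c(1.1, 1.9, 3.2, 3.8)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res2 <- linear_fit(x, y)
  expect_equal(unname(res2$effect["intercept"]), beta[1], tolerance = 1e-12)
  expect_equal(unname(res2$effect["slope"]), beta[2], tolerance = 1e-12)
  # independent noise: R^2 collapses with n
  set.seed(21)
  xn <- rnorm(1000); yn <- rnorm(1000)
  expect_lt(unname(linear_fit(xn, yn)$effect["r_squared"]), 0.01)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "variance")
})

test_that("R^2 is invariant to affine rescaling of x and y", {
  set.seed(9)
  x <- rnorm(15); y <- 0.6 * x + rnorm(15, 0, 0.5)
  r0 <- unname(linear_fit(x, y)$effect["r_squared"])
  r1 <- unname(linear_fit(3 * x - 7, -2 * y + 4)$effect["r_squared"])
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("post-hoc power is calibrated at the null and saturates at huge effects", {
  p_null <- posthoc_power("ranksum",
                          list(mean_a = 0, sd_a = 1, mean_b = 0, sd_b = 1,
                               n_a = 10, n_b = 10),
                          n_sims = 2000L, seed = 2L)
  expect_lt(abs(p_null - 0.05), 0.03)    # exact test is mildly conservative
  p_huge <- posthoc_power("ranksum",
                          list(mean_a = 0, sd_a = 1, mean_b = 10, sd_b = 1,
                               n_a = 5, n_b = 5),
                          n_sims = 1000L, seed = 2L)
  expect_gt(p_huge, 0.95)
  # moderate effect: two independent Monte-Carlo runs agree
  pars <- list(mean_a = 0, sd_a = 1, mean_b = 1, sd_b = 1, n_a = 5, n_b = 5)
  p1 <- posthoc_power("ranksum", pars, n_sims = 4000L, seed = 31L)
  p2 <- posthoc_power("ranksum", pars, n_sims = 4000L, seed = 77L)
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("simulated cohorts flow through the full analysis stage", {
  coh <- simulate_cohort(n_subjects = 10L, seed = 4L)
  expect_identical(nrow(coh), 10L * 5L * 5L)
  expect_true(all(coh$followup_years > 0.5))
  out <- analyze_cohort(coh, seed = 4L)
  expect_gt(out$n_tests, 0)
  expect_true(all(vapply(out$stability, function(s) s$p_value, 0) >= 0))
  expect_true(all(vapply(out$stability, function(s) s$p_value, 0) <= 1))
  expect_false(is.null(out$association))
  expect_identical(out$association$ols$n, 10L)
  # a strong induced drift is detected by the stability tests
  coh2 <- simulate_cohort(n_subjects = 10L, seed = 4L,
                          annual_drift = c(el_tot_mean = 0.5))
  out2 <- analyze_cohort(coh2, seed = 4L)
  p_drift <- out2$stability[["connection.el_tot_mean"]]$p_value
  expect_lt(p_drift, 0.05)
})
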