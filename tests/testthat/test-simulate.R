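test_that("the Mann-Whitney AUC agrees with brute-force pair counting", {
  expect_identical(empirical_auc(c(2, 3), c(1, 2.5)), 0.75)
  expect_identical(empirical_auc(c(5, 6), c(1, 2)), 1)
  expect_identical(empirical_auc(c(1, 1, 1), c(1, 1)), 0.5)  # all tied
  set.seed(20)
  for (i in 1:25) {
    cases <- sample(1:6, sample(2:8, 1), replace = TRUE)     # many ties
    controls <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(empirical_auc(cases, controls),
                 auc_pair_count(cases, controls), tolerance = 1e-14)
  }
  expect_error(empirical_auc(numeric(0), 1:3), "nonempty")
})

test_that("score simulation is reproducible and hits its targets", {
  d <- roc_design(0.80, 0.82, "continuous", rho = 0.3)
  a <- simulate_paired_scores(d, 50, seed = 11)
  b <- simulate_paired_scores(d, 50, seed = 11)
  expect_identical(a, b)
  # large-sample empirical AUCs approach the design AUCs
  big <- simulate_paired_scores(d, 1e5, seed = 3)
  expect_equal(empirical_auc(big$cases[, 1], big$controls[, 1]), 0.80,
               tolerance = 0.005)
  expect_equal(empirical_auc(big$cases[, 2], big$controls[, 2]), 0.82,
               tolerance = 0.005)
  # uncorrelated design gives near-zero sample inter-test correlation
  d0 <- roc_design(0.80, 0.82, "continuous", rho = 0)
  s0 <- simulate_paired_scores(d0, 1e4, seed = 5)
  expect_lt(abs(cor(s0$cases[, 1], s0$cases[, 2])), 3 / sqrt(1e4))
  expect_lt(abs(cor(s0$controls[, 1], s0$controls[, 2])), 3 / sqrt(1e4))
  # correlated design reproduces the requested correlation
  d8 <- roc_design(0.80, 0.82, "continuous", rho = 0.8)
  s8 <- simulate_paired_scores(d8, 1e4, seed = 5)
  expect_equal(cor(s8$cases[, 1], s8$cases[, 2]), 0.8, tolerance = 0.03)
})

test_that("unequal scale ratios shift case means and SDs as parameterized", {
  d <- roc_design(0.90, 0.82, "discrete", rho = 0.3, B1 = 2, B2 = 1)
  s <- simulate_paired_scores(d, 2e4, seed = 9)
  # controls standard normal; cases mean A/B, SD 1/B
  A1 <- sqrt(5) * qnorm(0.90)
  expect_equal(mean(s$cases[, 1]), A1 / 2, tolerance = 0.02)
  expect_equal(sd(s$cases[, 1]), 0.5, tolerance = 0.02)
  expect_equal(empirical_auc(s$cases[, 1], s$controls[, 1]), 0.90,
               tolerance = 0.01)
})

test_that("the simulated sampling variance matches the continuous formula", {
  # n * Var(theta-hat) against the analytic per-case variance at AUC = 0.80
  d <- roc_design(0.80, 0.80, "continuous", rho = 0.3)
  set.seed(31)
  n <- 500
  th <- replicate(2000, {
    s <- simulate_paired_scores(d, n)
    empirical_auc(s$cases[, 1], s$controls[, 1])
  })
  expect_equal(n * var(th), hm_variance_single(0.80, 1), tolerance = 0.1)
  # the rating-data formula is a conservative envelope for this estimator
  expect_gt(om_variance_single(binormal_from_auc(0.80), 1), n * var(th))
})

test_that("the power validator is seeded, bounded and honest about one draw", {
  d <- roc_design(0.80, 0.90, "continuous", rho = 0.8)
  one <- estimate_actual_power(d, n_pos = 36, replications = 1, seed = 2)
  expect_true(one$rejection_rate %in% c(0, 1))
  r1 <- estimate_actual_power(d, n_pos = 36, replications = 50, seed = 4)
  r2 <- estimate_actual_power(d, n_pos = 36, replications = 50, seed = 4)
  expect_identical(r1$rejection_rate, r2$rejection_rate)
  expect_equal(r1$mc_se, sqrt(r1$rejection_rate * (1 - r1$rejection_rate) / 50))
  # simulate() method dispatches to the validator
  r3 <- simulate(d, nsim = 50, seed = 4, n_pos = 36)
  expect_identical(r3$rejection_rate, r1$rejection_rate)
  expect_output(print(r3), "rejection rate")
})

test_that("rating-mode discretization attenuates the empirical AUC", {
  d <- roc_design(0.80, 0.82, "discrete", rho = 0.3)
  r <- estimate_actual_power(d, n_pos = 400, replications = 100, seed = 8,
                             rating_levels = 5)
  # five categories lose some discrimination relative to the latent scores
  expect_lt(r$mean_auc[1], 0.80)
  expect_gt(r$mean_auc[1], 0.74)
  expect_error(estimate_actual_power(d, n_pos = 50, replications = 10,
                                     rating_levels = 1), "rating_levels")
})
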