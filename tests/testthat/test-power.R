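test_that("required sample sizes hit the reference designs", {
  expect_identical(required_n(roc_design(0.80, 0.82, "discrete", rho = 0.3))$n_pos,
                   3709L)
  expect_identical(required_n(roc_design(0.80, 0.84, "discrete", rho = 0.3))$n_pos,
                   919L)
  expect_identical(required_n(roc_design(0.80, 0.82, "continuous", rho = 0.8))$n_pos,
                   909L)
})

test_that("analytic power inverts the sample-size solve", {
  d <- roc_design(0.80, 0.82, "discrete", rho = 0.3)
  expect_equal(power_at_n(d, 2793), 0.680, tolerance = 5e-4)
  expect_gte(power_at_n(d, 3709), 0.800)
  expect_lt(power_at_n(d, 3709), 0.8005)
  expect_lt(power_at_n(d, 3708), 0.800)
  # monotone limits
  expect_gt(power_at_n(d, 1e7), 0.999999)
  expect_gte(power_at_n(d, 5), d$alpha / 2)
  expect_lt(power_at_n(d, 5), 1)
})

test_that("sample size responds to design knobs in the right direction", {
  n2 <- required_n(roc_design(0.80, 0.82, "discrete", rho = 0.3))$n_pos
  # one-sided tests need fewer cases
  n1 <- required_n(roc_design(0.80, 0.82, "discrete", rho = 0.3, sides = 1))$n_pos
  expect_lt(n1, n2)
  # higher target power needs more
  n9 <- required_n(roc_design(0.80, 0.82, "discrete", rho = 0.3), power = 0.9)$n_pos
  expect_gt(n9, n2)
  # unequal allocation: controls scale with R
  nr <- required_n(roc_design(0.80, 0.84, "discrete", rho = 0.3, R = 2))
  expect_identical(nr$n_neg, as.integer(ceiling(2 * nr$n_pos)))
  # a design with equal areas cannot be powered
  expect_error(required_n(roc_design(0.80, 0.80, "discrete", rho = 0.3)),
               "infeasible")
})

test_that("attrition arithmetic inflates enrollment by the dropout rate", {
  a <- attrition_adjust(3709, 0.2)
  expect_identical(a$diss, 4637L)
  expect_identical(a$ed, 928L)
  b <- attrition_adjust(919, 0.2)
  expect_identical(c(b$diss, b$ed), c(1149L, 230L))
  z <- attrition_adjust(100, 0)
  expect_identical(c(z$diss, z$ed), c(100L, 0L))
  expect_error(attrition_adjust(100, 1), "dropout_rate")
  # invariants: diss >= n, ed = diss - n, vectorized
  v <- attrition_adjust(c(7, 50, 3709), 0.15)
  expect_true(all(v$diss >= c(7, 50, 3709)))
  expect_identical(v$ed, v$diss - c(7L, 50L, 3709L))
})

test_that("design validation rejects out-of-range parameters", {
  expect_error(roc_design(0.80, 1.2), "between 0 and 1")
  expect_error(roc_design(0.80, 0.82, rho = 1), "rho_pos")
  expect_error(roc_design(0.80, 0.82, alpha = 0), "alpha")
  expect_error(roc_design(0.80, 0.82, target_power = 0.04), "target_power")
  expect_error(roc_design(0.80, 0.82, "continuous", fpr_hi = 0.5),
               "full FPR range")
  expect_error(roc_design(0.80, 0.82, dropout_rate = 1), "dropout_rate")
})

test_that("design methods expose coefficients and predictions", {
  d <- roc_design(0.80, 0.84, "discrete", rho = 0.5)
  cf <- coef(d)
  expect_equal(unname(cf["A1"]), sqrt(2) * qnorm(0.80))
  expect_equal(predict(d, c(500, 1000)),
               c(power_at_n(d, 500), power_at_n(d, 1000)))
  s <- summary(d)
  expect_s3_class(s, "summary.roc_design")
  expect_identical(s$n$n_pos, required_n(d)$n_pos)
  expect_output(print(s), "V0")
})
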