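test_that("a single-cell grid yields one row per power level", {
  g <- scenario_grid(delta = 0.04, rho = 0.3, data_type = "discrete",
                     power_levels = c(0.8, 0.9, 0.95))
  res <- run_grid(g)
  expect_identical(nrow(res), 3L)
  expect_identical(res$n_pos[res$tp == 0.8], 919L)
  expect_true(all(res$power >= res$tp))
})

test_that("the factorial grid reproduces the reference extremes", {
  res <- run_grid(scenario_grid(power_levels = 0.8))
  expect_identical(nrow(res), 30L)
  s <- grid_summary(res, 0.8)
  expect_identical(s$n_max, 3709L)
  expect_identical(s$n_min, 36L)
  expect_identical(s$fold, 103)
  # continuous data never needs more cases than discrete in any cell
  disc <- res[res$data_type == "discrete", ]
  cont <- res[res$data_type == "continuous", ]
  m <- merge(disc, cont, by = c("delta", "rho", "tp"))
  expect_identical(nrow(m), 15L)
  expect_true(all(m$n_pos.y <= m$n_pos.x))
  # required n shrinks with larger differences and stronger correlation
  for (dt in c("discrete", "continuous")) {
    sub <- res[res$data_type == dt, ]
    for (r in unique(sub$rho)) {
      along_delta <- sub[sub$rho == r, ]
      expect_true(all(diff(along_delta$n_pos[order(along_delta$delta)]) < 0))
    }
    for (dd in unique(sub$delta)) {
      along_rho <- sub[sub$delta == dd, ]
      expect_true(all(diff(along_rho$n_pos[order(along_rho$rho)]) < 0))
    }
  }
})

test_that("efficiency summaries match the headline percent reductions", {
  expect_identical(percent_reduction(1899, 3709), 49)
  expect_identical(percent_reduction(909, 2807), 68)
  expect_identical(percent_reduction(2807, 3709), 24)
  expect_identical(percent_reduction(909, 1899), 52)
})

test_that("infeasible cells become error rows, not omissions", {
  res <- run_grid(scenario_grid(delta = c(0, 0.04), rho = 0.3,
                                data_type = "discrete", power_levels = 0.8))
  expect_identical(nrow(res), 2L)
  bad <- res[res$delta == 0, ]
  expect_true(is.na(bad$n_pos))
  expect_match(bad$error, "infeasible")
  expect_identical(res$n_pos[res$delta == 0.04], 919L)
})

test_that("scenario results round-trip through CSV and serialize to JSON", {
  res <- run_grid(scenario_grid(delta = c(0.02, 0.1), rho = c(0.3, 0.8),
                                power_levels = c(0.8, 0.9)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_scenario_csv(res, csv)
  back <- read_scenario_csv(csv)
  expect_equal(as.data.frame(back), as.data.frame(res), tolerance = 1e-12)
  json <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(res, json)
  doc <- jsonlite::read_json(json)
  expect_identical(doc$metadata$conventions$null_anchor, "auc1")
  expect_identical(length(doc$scenarios), 8L)
})

test_that("power curves rise monotonically and locate the 80% enrollment", {
  d <- roc_design(0.80, 0.82, "discrete", rho = 0.3)
  pc <- power_curve(d, seq(500, 6000, by = 250))
  expect_true(all(diff(pc$power) > 0))
  # enrollment (dropout-inflated, both groups) at the 80%-power size
  n <- required_n(d)
  expect_identical(n$diss_total, 9274L)
  expect_error(power_curve(d, c(100, 90)), "increasing")
})
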