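test_that("reference fixture conserves retinol exactly in every row", {
  ref <- reference_table5()
  expect_equal(nrow(ref), 7)
  expect_equal(ref$rt_bound + ref$rt_free, rep(1.73, 7))
})

test_that("percent_change matches the published effect metrics", {
  expect_equal(round(percent_change(0.56, 0.78), 1), 39.3)
  expect_equal(round(percent_change(2.2, 1.0), 1), -54.5)
  expect_equal(round(percent_change(0.57, 0.45), 1), -21.1)
  expect_equal(round(percent_change(6.0, 7.7), 1), 28.3)
  expect_equal(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), class = "retikin_validation_error")
})

test_that("headline metric comes from the fixture's free-retinol column", {
  expect_equal(round(headline_free_retinol_change(-30), 1), 39.3)
  expect_equal(headline_free_retinol_change(0), 0)
  expect_error(headline_free_retinol_change(-32),
               class = "retikin_validation_error")
})

test_that("fold_to_percent supports both conventions and inverts cleanly", {
  expect_equal(fold_to_percent(-1.32), -32)
  expect_equal(fold_to_percent(1.11), 11, tolerance = 1e-12)
  expect_equal(fold_to_percent(-1.32, "ratio"), (1 / 1.32 - 1) * 100)
  expect_equal(fold_to_percent(1.5, "ratio"), 50)
  expect_error(fold_to_percent(-0.5), class = "retikin_validation_error")
  expect_error(fold_to_percent(0), class = "retikin_validation_error")
  # exact inverse under the symmetric convention
  for (pct in c(-50, -32, -0.5, 0, 11, 40)) {
    expect_equal(fold_to_percent(percent_to_fold(pct)), pct)
  }
})

test_that("exact scans conserve retinol and decrease free retinol with RBP4", {
  sc <- scan_rbp4(default_params, levels = c(50, 30, 0, -30, -50),
                  method = "exact")
  expect_equal(sc$rt_bound + sc$rt_free, rep(1.73, 5), tolerance = 1e-9)
  expect_equal(sc$p1_total, 3.23 * (1 + sc$level_percent / 100))
  expect_equal(sc$pct_change_free_vs_reference[sc$level_percent == 0], 0)
  ord <- order(sc$level_percent)
  expect_true(all(diff(sc$rt_free[ord]) < 0))
  expect_gt(sc$rt_free[sc$level_percent == -30],
            sc$rt_free[sc$level_percent == 0])
  expect_true(all(sc$status == "ok"))
})

test_that("chain scans flag the breakdown level instead of fabricating rows", {
  sc <- scan_rbp4(default_params, levels = c(50, 0, -30), method = "chain")
  up <- sc[sc$level_percent == 50, ]
  expect_equal(up$status, "chain-breakdown")
  expect_true(is.na(up$rt_free))
  ok <- sc[sc$status == "ok", ]
  expect_equal(ok$rt_bound + ok$rt_free, rep(1.73, nrow(ok)),
               tolerance = 1e-12)
  # chain partition: rt_free/rt_bound = kd1/free_p1
  res30 <- run_chain(parameter_set(p1_total = 3.23 * 0.7))
  r30 <- sc[sc$level_percent == -30, ]
  expect_equal(r30$rt_free / r30$rt_bound, 0.664 / res30$free_p1,
               tolerance = 1e-12)
})

test_that("scans require the reference level", {
  expect_error(scan_rbp4(default_params, levels = c(-30, 30)),
               class = "retikin_validation_error")
})

test_that("comparison against the fixture reports signed discrepancies", {
  # fixture vs itself: all differences vanish
  self <- reference_table5()
  self$pct_change_free_vs_reference <- NA
  self$method <- "exact"; self$status <- "ok"
  class(self) <- c("perturbation_scan", "data.frame")
  cmp0 <- compare_to_table5(self)
  expect_true(all(cmp0$comparison$diff_free == 0))
  expect_equal(cmp0$fixture_mass_balance, rep(1.73, 7))

  # the exact solver is expected to disagree with the printed columns;
  # the report carries sign and magnitude (regression-snapshot level check)
  sc <- scan_rbp4(default_params, levels = c(0, -30), method = "exact")
  cmp <- compare_to_table5(sc)
  expect_true(all(abs(cmp$comparison$diff_free) > 0))
  expect_lt(cmp$comparison$diff_free[cmp$comparison$level_percent == 0], 0)

  expect_error(compare_to_table5(
    scan_rbp4(default_params, levels = c(0, -32), method = "exact")),
    class = "retikin_validation_error")
})
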