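test_that("parameter draws are seeded, truncated and centred correctly", {
  cfg <- mc_config(n_draws = 1000, seed = 7)
  draws <- sample_parameter_sets(default_params, cfg)
  expect_length(draws, 1000)
  rt <- vapply(draws, function(p) p$rt_total, numeric(1))
  expect_true(all(rt >= 0))
  # sample mean within 3 standard errors of 1.73 (truncation bias at this
  # mean/sd ratio is far below one SE)
  expect_lt(abs(mean(rt) - 1.73), 3 * 0.34 / sqrt(1000))
  # constants without a reported SD use default_cv x mean
  kd1 <- vapply(draws, function(p) p$kd1, numeric(1))
  expect_lt(abs(sd(kd1) - 0.1 * 0.664), 0.02)

  # bit-identical regeneration under the same seed
  draws2 <- sample_parameter_sets(default_params, cfg)
  expect_identical(
    vapply(draws, function(p) p$kd3, numeric(1)),
    vapply(draws2, function(p) p$kd3, numeric(1)))
  # and the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_parameter_sets(default_params,
                                                mc_config(5, seed = 3)))
  expect_identical(runif(1), before)
})

test_that("zero-SD draws collapse to the means", {
  p <- default_params
  p$sd[] <- 0
  draws <- sample_parameter_sets(p, mc_config(10, seed = 1, default_cv = 0))
  for (d in draws) {
    expect_identical(as_config(d), as_config(p))
  }
})

test_that("uncertainty propagation: degenerate, reproducible, 1/sqrt(n)", {
  p <- default_params
  p$sd[] <- 0
  cfg0 <- mc_config(20, seed = 5, default_cv = 0)
  deg <- propagate_uncertainty(p, cfg0, scenario = -30, method = "exact")
  expect_equal(deg$sd, 0)
  point <- deg$mean

  cfg <- mc_config(400, seed = 11)
  s1 <- propagate_uncertainty(default_params, cfg, -30, "exact")
  s1b <- propagate_uncertainty(default_params, cfg, -30, "exact")
  expect_identical(s1$draws, s1b$draws)          # seeded determinism
  expect_equal(s1$n_infeasible, 0)               # exact method always solves
  # the spread bracket contains the all-means point estimate
  expect_gt(point, s1$q025)
  expect_lt(point, s1$q975)

  # Monte-Carlo error scaling: SEM at 4n is about half the SEM at n
  s4 <- propagate_uncertainty(default_params, mc_config(1600, seed = 11),
                              -30, "exact")
  sem_ratio <- (s1$sd / sqrt(s1$n_ok)) / (s4$sd / sqrt(s4$n_ok))
  expect_equal(sem_ratio, 2, tolerance = 0.15)
})

test_that("chain-method propagation counts infeasible draws", {
  # push RBP4 up so that a good share of draws break the stepwise chain
  p <- parameter_set(p1_total = 4.6)
  s <- propagate_uncertainty(p, mc_config(200, seed = 3), -30, "chain")
  expect_gt(s$n_infeasible, 0)
  expect_equal(s$n_ok + s$n_infeasible, 200)
})

test_that("titration generation is exact at zero noise and seeded otherwise", {
  grid <- seq(0.2, 5, length.out = 10)
  clean <- generate_titration(0.664, 3.23, grid, noise_sd = 0)
  expect_equal(clean$observed,
               vapply(grid, solve_binary, numeric(1), 3.23, 0.664))
  noisy1 <- generate_titration(0.664, 3.23, grid, 0.02, seed = 42)
  noisy2 <- generate_titration(0.664, 3.23, grid, 0.02, seed = 42)
  expect_identical(noisy1$observed, noisy2$observed)
  expect_true(all(noisy1$observed >= 0))
  empty <- generate_titration(0.664, 3.23, numeric(0))
  expect_length(empty$observed, 0)
})

test_that("fit_kd recovers the truth exactly at zero noise", {
  grid <- seq(0.2, 5, length.out = 10)
  for (kd in c(0.664, 0.20)) {
    d <- generate_titration(kd, 3.23, grid, 0)
    fit <- fit_kd(d)
    expect_equal(fit$kd_estimate, kd, tolerance = 1e-6)
  }
  expect_error(fit_kd(generate_titration(0.664, 3.23, c(4, 5, 6), 0)),
               class = "retikin_validation_error")
  expect_error(fit_kd(generate_titration(0.664, 3.23, c(0.1, 0.2), 0)),
               class = "retikin_validation_error")
})

test_that("fit_kd parameter recovery over seeded noisy replicates", {
  grid <- seq(0.2, 5, length.out = 20)
  est <- vapply(1:200, function(i) {
    d <- generate_titration(0.664, 3.23, grid, noise_sd = 0.02, seed = i)
    fit_kd(d)$kd_estimate
  }, numeric(1))
  expect_lt(abs(median(est) - 0.664) / 0.664, 0.05)
  # alternate literature value recovered to the same tolerance
  est2 <- vapply(1:200, function(i) {
    d <- generate_titration(0.20, 3.23, grid, noise_sd = 0.02, seed = i)
    fit_kd(d)$kd_estimate
  }, numeric(1))
  expect_lt(abs(median(est2) - 0.20) / 0.20, 0.05)
})
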