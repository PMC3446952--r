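test_that("closed-form binary solution matches an independent root finder", {
  # frozen from the scalar uniroot oracle on b*Kd = (l-b)(p-b)
  expect_equal(solve_binary(1.73, 3.23, 0.664), 1.289027905705,
               tolerance = 1e-10)
  set.seed(11)
  for (i in 1:40) {
    l <- runif(1, 0, 5); p <- runif(1, 0, 5)
    kd <- exp(runif(1, log(1e-4), log(100)))
    b <- solve_binary(l, p, kd)
    expect_equal(b, binary_uniroot(l, p, kd), tolerance = 1e-9)
    expect_equal(b, solve_binary(p, l, kd))          # symmetry
    expect_true(b >= 0 && b <= min(l, p) + 1e-12)
  }
  expect_equal(solve_binary(1.73, 3.23, 0), 1.73)    # infinite affinity
  expect_equal(solve_binary(0, 3.23, 0.5), 0)
})

test_that("solver agrees with closed form on one-reaction networks", {
  net <- binding_network(
    data.frame(name = c("L", "P"), total = c(1.73, 3.23)),
    data.frame(lhs = "L", rhs = "P", complex = "L.P", kd = 0.664))
  st <- solve_equilibrium(net)
  expect_true(st$converged)
  expect_equal(unname(st$complexes["L.P"]), solve_binary(1.73, 3.23, 0.664),
               tolerance = 1e-9)
  ob <- oracle_bisection(net)
  expect_equal(unname(ob$complexes["L.P"]), solve_binary(1.73, 3.23, 0.664),
               tolerance = 1e-9)
})

test_that("default carrier network: conservation, mass action, oracle agreement", {
  net <- build_network(default_params)
  st <- solve_equilibrium(net)
  expect_true(st$converged)
  expect_lt(max(abs(st$residuals)), 1e-10)
  expect_lt(mass_action_rel_error(net, st), 1e-9)
  ob <- oracle_bisection(net)
  expect_equal(st$free, ob$free, tolerance = 1e-9)
  # regression snapshot (solver value, not a literature value)
  expect_equal(unname(st$free["Rt"]), 0.160400460163, tolerance = 1e-8)
  # the ternary sink pulls retinol beyond the binary-only prediction
  rt_free_binary <- 1.73 - solve_binary(1.73, 3.23, 0.664)
  expect_lt(unname(st$free["Rt"]), rt_free_binary)
})

test_that("solver == bisection oracle on randomized small networks", {
  set.seed(101)
  for (i in 1:25) {
    net <- random_network()
    st <- solve_equilibrium(net)
    ob <- oracle_bisection(net)
    expect_true(st$converged)
    expect_lt(max(abs(st$residuals)), 1e-10)
    expect_lt(mass_action_rel_error(net, st), 1e-9)
    expect_equal(st$free, ob$free, tolerance = 1e-9)
  }
})

test_that("determinism: identical inputs give bit-identical states", {
  net <- build_network(default_params)
  a <- solve_equilibrium(net)
  b <- solve_equilibrium(net)
  expect_identical(a, b)
})

test_that("no-binding and infinite-affinity limits", {
  p <- default_params
  # all Kds enormous: free == totals, complexes ~ 0
  loose <- parameter_set(kd1 = 1e9, kd2 = 1e9, kd3 = 1e9)
  st <- solve_equilibrium(build_network(loose))
  expect_equal(unname(st$free),
               c(p$rt_total, p$p1_total, p$p2_total), tolerance = 1e-6)
  expect_true(all(st$complexes < 1e-6))
  # kd2, kd3 -> infinity reduces the network to the binary reaction
  reduced <- parameter_set(kd2 = 1e6, kd3 = 1e6)
  st2 <- solve_equilibrium(build_network(reduced))
  expect_equal(unname(st2$free["Rt"]),
               1.73 - solve_binary(1.73, 3.23, 0.664), tolerance = 1e-4)
})

test_that("free retinol is monotone in totals and Kd1", {
  rt_free_at <- function(p) {
    unname(solve_equilibrium(build_network(p))$free["Rt"])
  }
  p1_grid <- seq(0.5, 6, by = 0.5)
  v1 <- sapply(p1_grid, function(x) rt_free_at(parameter_set(p1_total = x)))
  expect_true(all(diff(v1) < 0))   # more carrier, less free retinol
  p2_grid <- seq(0.5, 8, by = 0.5)
  v2 <- sapply(p2_grid, function(x) rt_free_at(parameter_set(p2_total = x)))
  expect_true(all(diff(v2) <= 1e-12))
  kd1_grid <- c(0.05, 0.1, 0.2, 0.4, 0.664, 1, 2, 5)
  v3 <- sapply(kd1_grid, function(x) rt_free_at(parameter_set(kd1 = x)))
  expect_true(all(diff(v3) > 0))   # weaker binding, more free retinol
})

test_that("zero-total species stay at zero without breaking the solve", {
  net <- binding_network(
    data.frame(name = c("L", "P"), total = c(0, 2)),
    data.frame(lhs = "L", rhs = "P", complex = "L.P", kd = 0.1))
  st <- solve_equilibrium(net)
  expect_equal(unname(st$free), c(0, 2))
  expect_equal(unname(st$complexes), 0)
})

test_that("state dumps to CSV with species and complex blocks", {
  net <- build_network(default_params)
  st <- solve_equilibrium(net)
  df <- state_to_csv(st, net)
  expect_equal(sum(df$kind == "species"), 3)
  expect_equal(sum(df$kind == "complex"), 3)
  expect_true(all(abs(df$residual[df$kind == "species"]) < 1e-10))
})
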