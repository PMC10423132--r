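# Fixed-step RK4 integration, seasonal scenarios, and their invariants.

test_that("integrator reproduces the closed forms at the default step", {
  p <- fish_params(6000)
  sim <- rk4_integrate(function(s, ctrl) rhs_single(p, s), p$x0,
                       horizon = 12, step = 0.01)
  expect_lt(max_rel_err(sim$states[, 1], solution_single(p, sim$t)), 1e-6)
  pc <- coupled_params(0.8, 780500, -390.25, 10000)
  simc <- rk4_integrate(function(s, ctrl) rhs_coupled(pc, s, 1000), pc$x0,
                        horizon = 24, step = 0.01)
  expect_lt(max_rel_err(simc$states[, 1],
                        solution_coupled(pc, 1000, simc$t)), 1e-6)
})

test_that("halving the step leaves the terminal state unchanged to 1e-6", {
  sc1 <- fixture_single(step = 0.01)
  sc2 <- fixture_single(step = 0.005)
  x1 <- tail(run_scenario(sc1)$x1, 1)
  x2 <- tail(run_scenario(sc2)$x1, 1)
  expect_equal(x1 / x2, 1, tolerance = 1e-6)
})

test_that("unstable mutualistic overgrowth aborts with a diagnostic", {
  p <- coexist_params(1, 1, 100, 100, sqrt(2), sqrt(2), 50, 50)
  expect_error(
    rk4_integrate(function(s, ctrl) rhs_coexist(p, s[1], s[2]),
                  c(50, 50), horizon = 60, step = 0.01),
    class = "growthreg_unstable")
})

test_that("trajectories are continuous across season boundaries on a uniform grid", {
  tr <- run_scenario(fixture_coupled(v_level = 1000, mode = "closed_loop"))
  expect_equal(diff(tr$t), rep(0.01, nrow(tr) - 1), tolerance = 1e-9)
  expect_false(any(duplicated(tr$t)))
  # state increments are bounded by the largest possible rate times the step
  max_rate <- 0.8 * max(tr$x1) * 2
  expect_true(all(abs(diff(tr$x1)) <= max_rate * 0.01))
  expect_true(all(tr$x1 >= 0))
  expect_equal(sort(unique(tr$season_index)), 1:9)
  # coupling jumps at season boundaries are allowed and expected
  expect_gt(max(abs(diff(tr$alpha_applied)), na.rm = TRUE), 1)
})

test_that("a decoupled coexistence run equals two independent single runs", {
  p <- coexist_params(0.8, 0.3, 1000, 400, 0, 0, 50, 20)
  sc <- scenario("coexist", p, list(season(20, "decoupled")), step = 0.01)
  tr <- run_scenario(sc)
  s1 <- run_scenario(scenario("single", single_params(0.8, 1000, 50),
                              list(season(20, "decoupled")), step = 0.01))
  s2 <- run_scenario(scenario("single", single_params(0.3, 400, 20),
                              list(season(20, "decoupled")), step = 0.01))
  expect_equal(tr$x1, s1$x1, tolerance = 1e-12)
  expect_equal(tr$x2, s2$x1, tolerance = 1e-12)
})

test_that("an all-decoupled scenario is a plain single-species run", {
  sc <- scenario("coupled", coupled_params(0.8, 780500, -780.5, 6000),
                 list(season(6, "decoupled"), season(6, "decoupled")),
                 step = 0.01, v_level = 1000)
  tr <- run_scenario(sc)
  expect_lt(max_rel_err(tr$x1, solution_single(fish_params(6000), tr$t)),
            1e-6)
})

test_that("scenario construction validates its inputs", {
  expect_error(season(6, "open_loop"), "alpha")
  expect_error(season(6, "closed_loop"), "reference_fraction")
  expect_error(season(6, "closed_loop", reference_fraction = 1.2), "0, 1")
  expect_error(season(-1, "decoupled"), "duration")
  expect_error(scenario("single", fish_params(), list()), "non-empty")
  expect_error(scenario("coupled", fish_params(),
                        list(season(6, "decoupled"))), "coupled_params")
  expect_error(scenario("coupled", coupled_params(1, 1, 0, 1),
                        list(season(6, "open_loop", alpha = -1))),
               "v_level")
  sc <- scenario("single", fish_params(), list(season(5, "decoupled"),
                                               season(7, "decoupled")))
  expect_equal(sc$horizon, 12)
})

test_that("trajectory CSV round-trips and is byte-stable", {
  tr <- run_scenario(fixture_single(step = 0.1))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory(tr, f1)
  write_trajectory(run_scenario(fixture_single(step = 0.1)), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- utils::read.csv(f1)
  expect_equal(back$x1, tr$x1, tolerance = 1e-12)
  expect_equal(names(back),
               c("t", "x1", "alpha_applied", "reference", "season_index"))
  unlink(c(f1, f2))
})
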