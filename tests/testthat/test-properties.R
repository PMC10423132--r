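# Closed-form dynamic properties: equilibria, final values, inflection
# points, characteristic times, and their defining identities.

test_that("single-species equilibria are 0 and N, and are roots of the rate", {
  p <- fish_params()
  eq <- equilibria_single(p)
  expect_equal(unname(eq), c(0, 780500))
  expect_equal(unname(rhs_single(p, eq)), c(0, 0))
  expect_equal(unname(equilibria_single(single_params(1, 1, 0.5))), c(0, 1))
  # away from the equilibria the rate is bounded away from zero on a fine grid
  xs <- c(seq(0.01, 0.95, by = 0.01), seq(1.05, 1.99, by = 0.01)) * p$N
  expect_true(all(abs(rhs_single(p, xs)) > 1e-6 * p$r * p$N))
})

test_that("final value equals N on both the growth and the decline branch", {
  expect_equal(final_value_single(fish_params(6000)), 780500)
  expect_equal(final_value_single(fish_params(1e6)), 780500)
  expect_error(final_value_single(fish_params(0)), "trivial")
  # numeric limit: the trajectory at 5 t* is within 0.1% of N
  p <- fish_params()
  expect_equal(solution_single(p, 5 * transitory_time_single(p)) / p$N, 1,
               tolerance = 1e-3)
})

test_that("inflection sits at N/2 and is absent for high starts", {
  expect_equal(inflection_single(fish_params(6000)), 390250)
  expect_true(is.na(inflection_single(fish_params(400000))))
  expect_true(is.na(inflection_single(fish_params(390250))))  # x0 = N/2
})

test_that("characteristic times satisfy their defining crossings exactly", {
  p <- fish_params()
  expect_equal(transitory_time_single(p), 11.81947, tolerance = 1e-6)
  expect_equal(time_to_inflection_single(p), 6.075573, tolerance = 1e-6)
  expect_equal(solution_single(p, transitory_time_single(p)), 0.99 * p$N)
  expect_equal(solution_single(p, time_to_inflection_single(p)), p$N / 2)
  # decline branch: crossing of 1.01 N
  pd <- fish_params(1e6)
  expect_equal(solution_single(pd, transitory_time_single(pd)), 1.01 * pd$N)
  expect_error(transitory_time_single(fish_params(780500)), "equilibrium")
  expect_true(is.na(time_to_inflection_single(fish_params(400000))))
})

test_that("rate_from_time inverts the characteristic-time formulas", {
  r <- rate_from_time(N = 5000, x0 = 500, target_time = 60, "transitory")
  expect_equal(r, log(891) / 60)
  expect_equal(r, 0.1132, tolerance = 1e-3)
  # round trip through the forward formula
  p <- single_params(r, 5000, 500)
  expect_equal(transitory_time_single(p), 60, tolerance = 1e-9)
  p2 <- single_params(rate_from_time(780500, 6000, 6.0756, "inflection"),
                      780500, 6000)
  expect_equal(time_to_inflection_single(p2), 6.0756, tolerance = 1e-9)
  # degenerate inversions are rejected
  expect_error(rate_from_time(2, 1, 1, "inflection"), "no inflection")
  expect_error(rate_from_time(5000, 5000, 10, "transitory"), "x0 = N")
})

test_that("coupled-model properties shift N to the effective capacity N + alpha*v", {
  p0 <- coupled_params(0.8, 780500, 0, 10000)
  expect_equal(unname(equilibria_coupled(p0, 1000)), c(0, 780500))
  pneg <- coupled_params(0.8, 780500, -390.25, 10000)
  eq <- equilibria_coupled(pneg, 1000)
  expect_equal(unname(eq), c(0, 390250))
  expect_equal(rhs_coupled(pneg, eq[["nontrivial"]], 1000), 0)
  expect_equal(final_value_coupled(pneg, 1000), 390250)
  expect_equal(inflection_coupled(pneg, 1000), 195125)
  # alpha > 0 raises the final value above N
  ppos <- coupled_params(0.5, 100, 0.5, 10)
  expect_equal(final_value_coupled(ppos, 10), 105)
  expect_equal(final_value_coupled(coupled_params(0.5, 100, 0, 10), 10), 100)
  # extinction branch: alpha <= -N/v gives 0 with a flag
  pext <- coupled_params(0.8, 780500, -780.5, 10000)
  fv <- final_value_coupled(pext, 1000)
  expect_equal(as.numeric(fv), 0)
  expect_true("extinction" %in% property_flags(fv))
  fv2 <- final_value_coupled(coupled_params(0.8, 100, -20, 10), 10)
  expect_equal(as.numeric(fv2), 0)  # alpha = -2N/v
  expect_true("lemma_condition_violated" %in%
                property_flags(equilibria_coupled(pext, 2000)))
})

test_that("coupled characteristic times reduce to the uncoupled ones and satisfy the 99% crossing", {
  p0 <- coupled_params(0.8, 780500, 0, 6000)
  ps <- fish_params(6000)
  expect_equal(transitory_time_coupled(p0, 1000),
               transitory_time_single(ps))
  expect_equal(time_to_inflection_coupled(p0, 1000),
               time_to_inflection_single(ps))
  pneg <- coupled_params(0.8, 780500, -390.25, 10000)
  ts <- transitory_time_coupled(pneg, 1000)
  expect_equal(solution_coupled(pneg, 1000, ts),
               0.99 * final_value_coupled(pneg, 1000))
  ti <- time_to_inflection_coupled(pneg, 1000)
  expect_equal(solution_coupled(pneg, 1000, ti),
               inflection_coupled(pneg, 1000))
  # extinction regime has no finite sigmoid times
  pext <- coupled_params(0.8, 780500, -780.5, 10000)
  expect_true(is.na(transitory_time_coupled(pext, 1000)))
  expect_true(is.na(time_to_inflection_coupled(pext, 1500)))
})

test_that("coexistence equilibria and final values follow the corrected closed forms", {
  # neutralism decouples
  pn <- coexist_params(1, 1, 300, 700, 0, 0, 10, 10)
  expect_equal(equilibria_coexist(pn)$nontrivial, c(300, 700))
  expect_equal(as.numeric(final_value_coexist(pn)), c(300, 700))
  # mutualism example
  pm <- coexist_params(1, 1, 100, 200, 0.5, 0.5, 10, 10)
  expect_equal(equilibria_coexist(pm)$nontrivial,
               c(266.6667, 333.3333), tolerance = 1e-6)
  # amensalism: (N1 + alpha1 N2, N2)
  pa <- coexist_params(0.8, 0.11, 780500, 5000, -78.05, 0, 1e4, 500)
  expect_equal(equilibria_coexist(pa)$nontrivial, c(390250, 5000))
  # symmetric competition
  pc <- coexist_params(1, 1, 100, 100, -0.5, -0.5, 10, 10)
  expect_equal(as.numeric(final_value_coexist(pc)),
               c(66.66667, 66.66667), tolerance = 1e-6)
  # product = 1 has no real solution
  p1 <- coexist_params(1, 1, 100, 100, 2, 0.5, 10, 10)
  expect_error(equilibria_coexist(p1), "no real solution")
  expect_error(final_value_coexist(p1), "no real solution")
})

test_that("coexistence extinction and overgrowth branches are flagged", {
  # amensalism with alpha1 = -2 N1/N2: species 1 dies, survivor at capacity
  pa <- coexist_params(0.8, 0.5, 1000, 500, -4, 0, 100, 50)
  fv <- final_value_coexist(pa)
  expect_equal(as.numeric(fv), c(0, 500))
  expect_true("extinction_species1" %in% property_flags(fv))
  # predation exterminating the prey: predator settles at its own capacity
  pp <- coexist_params(0.8, 0.5, 1000, 500, -3, 0.2, 100, 50)
  expect_equal(as.numeric(final_value_coexist(pp)), c(0, 500))
  # mutualism with product > 1 overgrows without bound
  pm <- coexist_params(1, 1, 100, 100, 2, 2, 10, 10)
  fvm <- final_value_coexist(pm)
  expect_true(all(is.infinite(fvm)))
  expect_true("unstable_overgrowth" %in% property_flags(fvm))
})

test_that("coexistence inflection points follow the closed form", {
  expect_equal(inflection_coexist(coexist_params(1, 1, 300, 700, 0, 0, 1, 1)),
               c(150, 350))
  pm <- coexist_params(1, 1, 100, 200, 0.5, 0.5, 10, 10)
  expect_equal(inflection_coexist(pm), c(300 / 3.75, 450 / 3.75))
  expect_error(inflection_coexist(coexist_params(1, 1, 1, 1, 2, 2, 1, 1)),
               "undefined")
})

test_that("non-trivial equilibria are roots of the rates and attract long integrations", {
  set.seed(7)
  for (i in 1:8) {
    p <- rand_coexist_stable()
    eq <- equilibria_coexist(p)$nontrivial
    # substitution residual, relative to the natural rate scale
    resid <- rhs_coexist(p, eq[1], eq[2]) / c(p$r1 * p$N1, p$r2 * p$N2)
    expect_lt(max(abs(resid)), 1e-9)
    fv <- as.numeric(final_value_coexist(p))
    sim <- rk4_integrate(function(s, ctrl) rhs_coexist(p, s[1], s[2]),
                         c(p$x01, p$x02), horizon = 400, step = 0.05)
    expect_equal(sim$states[nrow(sim$states), ] / fv, c(1, 1),
                 tolerance = 5e-3)
  }
})

test_that("single-species trajectories rise monotonically from below N", {
  set.seed(11)
  for (i in 1:5) {
    p <- rand_single()
    # up to the transitory time the growth increments stay strictly positive
    sim <- rk4_integrate(function(s, ctrl) rhs_single(p, s), p$x0,
                         horizon = transitory_time_single(p), step = 0.01)
    expect_true(all(diff(sim$states[, 1]) > 0))
    expect_true(all(sim$states >= 0))
  }
})

test_that("property reports assemble every closed-form quantity", {
  rep <- property_report(fish_params())
  expect_equal(rep$equilibria$nontrivial, 780500)
  expect_equal(rep$final_value, 780500)
  expect_equal(rep$inflection, 390250)
  expect_equal(rep$t_ip, 6.075573, tolerance = 1e-6)
  repc <- property_report(coupled_params(0.8, 780500, -390.25, 1e4), v = 1000)
  expect_equal(repc$final_value, 390250)
  repx <- property_report(coexist_params(1, 1, 100, 100, 2, 0.5, 1, 1))
  expect_true("no_real_solution" %in% repx$flags)
})
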