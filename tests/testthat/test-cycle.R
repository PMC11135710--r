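test_that("species eat their highest remaining preference", {
  expect_identical(active_resource(c(1, 2, 3), c(1, 2, 3)), 1L)
  expect_identical(active_resource(c(1, 2, 3), c(2, 3)), 2L)
  expect_identical(active_resource(c(3, 1, 2), 2), 2L)
  expect_identical(active_resource(c(1, 2, 3), integer()), NA_integer_)
})

test_that("phase solver matches closed forms and the ODE oracle", {
  # one species: t = ln(1 + c0/n0) / g
  g <- matrix(0.5, 1, 1)
  ev <- solve_phase(1 / 9, g, 1L, 1)
  expect_equal(ev$dt, log(10) / 0.5, tolerance = 1e-12)
  expect_identical(ev$depleted, 1L)

  # two species on one resource: 0.05(e^t - 1) + 0.05(e^{t/2} - 1) = 1,
  # checked against dense numerical integration of the ODEs
  pool <- new_species_pool(matrix(c(1.0, 0.5), 2, 1), matrix(1L, 2, 1))
  ev2 <- solve_phase(c(0.05, 0.05), pool$growth_rates, c(1L, 1L), 1)
  oracle <- ode_depletion_oracle(pool, c(0.05, 0.05), 1)
  expect_equal(ev2$dt, oracle$cycle_length, tolerance = 1e-6)
  # and satisfies the defining equation
  expect_lt(abs(0.05 * expm1(ev2$dt) + 0.05 * expm1(0.5 * ev2$dt) - 1), 1e-9)

  expect_error(solve_phase(0.1, g, NA_integer_, 1), "stalled|consumer")
})

test_that("a single-species growth cycle has the exact closed form", {
  pool <- pool_from_traits(species_traits(c(0.7, 0.7), c(1, 2), "A"))
  rec <- run_growth_cycle(pool, 1 / 9, c(0.4, 0.6))
  expect_equal(rec$cycle_length, log(10) / 0.7, tolerance = 1e-10)
  expect_equal(sum(rec$end_populations), 10 / 9, tolerance = 1e-10)
  # growth only within a cycle
  expect_true(all(rec$end_populations >= rec$start_populations))
})

test_that("zero-supply resources are depleted at time zero and excluded from niches", {
  pool <- pool_from_traits(species_traits(c(0.5, 0.5, 0.5), c(1, 2, 3), "A"))
  rec <- run_growth_cycle(pool, 1 / 9, c(0, 1, 0))
  expect_equal(rec$depletion_times[c(1, 3)], c(0, 0))
  expect_equal(rec$niches[[1]], 2L)
  expect_equal(rec$cycle_length, log(10) / 0.5, tolerance = 1e-10)
})

test_that("event-driven cycles conserve mass and match ODE integration", {
  set.seed(31)
  for (case in 1:8) {
    inst <- random_small_instance()
    rec <- run_growth_cycle(inst$pool, inst$n0, inst$supply)
    # mass balance: biomass gained equals total supply (yield 1)
    expect_lt(abs(sum(rec$end_populations) - sum(inst$n0) - 1), 1e-9)
    # depletion order consistent with sorted depletion times
    expect_equal(rec$depletion_order,
                 order(rec$depletion_times, seq_along(rec$depletion_times)))
    # cycle length is the last depletion
    expect_equal(rec$cycle_length, max(rec$depletion_times))
    # oracle equivalence to 1e-6 relative
    oracle <- ode_depletion_oracle(inst$pool, inst$n0, inst$supply)
    expect_equal(rec$depletion_times, oracle$depletion_times,
                 tolerance = 1e-6)
    expect_equal(rec$end_populations, oracle$end_populations,
                 tolerance = 1e-6)
    # niche durations partition the cycle
    expect_equal(sum(diff(rec$phase_boundaries)), rec$cycle_length)
  }
})

test_that("mortality divides populations and resets concentrations", {
  st <- apply_mortality_and_resupply(c(0.9, 0.2), c(0.3, 0.7))
  expect_equal(st$populations, c(0.09, 0.02))
  expect_equal(st$concentrations, c(0.3, 0.7))
  expect_equal(apply_mortality_and_resupply(0, c(1, 0))$populations, 0)
  expect_error(apply_mortality_and_resupply(1, c(1, 0), mortality = 1),
               "exceed 1")
  # repeated cycles: end-of-cycle biomass converges to the 10/9 fixed point
  pool <- pool_from_traits(species_traits(1, 1, "A"))
  n <- 0.77
  for (k in 1:60) {
    rec <- run_growth_cycle(pool, n, 1)
    n <- rec$end_populations / 10
  }
  expect_equal(rec$end_populations, 10 / 9, tolerance = 1e-10)
})

test_that("population fractions normalise biomass", {
  expect_equal(population_fractions(10 / 9), 1)
  expect_equal(population_fractions(c(0.6, 0.4)), c(0.6, 0.4))
  # at the steady-state total 10/9 the fraction is (9/10) n
  n <- 10 / 9 * c(0.3, 0.7)
  expect_equal(population_fractions(n), 0.9 * n)
  expect_error(population_fractions(c(0, 0)), "positive")
})

test_that("simultaneous depletion is handled as a single event", {
  # perfect mirror symmetry: both resources deplete at the same instant
  pool <- generate_fixtures("mirror-pair")
  rec <- run_growth_cycle(pool, c(1 / 18, 1 / 18), c(0.5, 0.5))
  expect_equal(rec$depletion_times[1], rec$depletion_times[2])
  expect_length(rec$phase_boundaries, 2)
  expect_equal(sum(rec$end_populations), 10 / 9, tolerance = 1e-9)
})
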