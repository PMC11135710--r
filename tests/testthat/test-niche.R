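test_that("the niche bound is 2^N - 1", {
  expect_identical(max_niche_count(3), 7L)
  expect_identical(max_niche_count(4), 15L)
  expect_identical(max_niche_count(5), 31L)
  expect_equal(round(100 * 23 / max_niche_count(5)), 74)
})

test_that("per-cycle niches follow the depletion order", {
  # R3 first, then R1, then R2
  n1 <- niches_of_cycle(c(2, 3, 1))
  expect_identical(n1$niche, c("1+2+3", "1+2", "2"))
  expect_equal(n1$duration, c(1, 1, 1))
  # R1 before R3: the two-resource niche becomes R2-and-R3
  n2 <- niches_of_cycle(c(1, 3, 2))
  expect_identical(n2$niche, c("1+2+3", "2+3", "2"))
  # single supplied resource
  n3 <- niches_of_cycle(c(0, 2.5, 0))
  expect_identical(n3$niche, "2")
  expect_error(niches_of_cycle(c(0, 0, 0)), "no supplied")
})

test_that("niche durations partition each cycle and tallies respect the bound", {
  set.seed(51)
  pool <- sample_pool(3, 20)
  sim <- run_serial_dilution(pool, sample_uniform_simplex(3, 400), 400)
  for (k in c(350, 375, 400)) {
    ns <- niches_of_cycle(sim$depletion_times[k, ])
    expect_equal(sum(ns$duration), sim$cycle_lengths[k], tolerance = 1e-9)
  }
  tal <- tally_niches(sim)
  expect_lte(nrow(tal$niches), max_niche_count(3))
  expect_identical(tal$max_niches, 7L)
  # a constant-supply single species run realizes exactly N niches
  pool1 <- pool_from_traits(species_traits(c(0.9, 0.3), c(1, 2), "A"))
  sim1 <- run_serial_dilution(pool1, c(0.5, 0.5), 50)
  tal1 <- tally_niches(sim1, window = 1)
  expect_identical(nrow(tal1$niches), 2L)
})

test_that("time on preferences reflects the supply regime", {
  # single species, single resource: all growth on rank 1, tau = cycle length
  pool1 <- pool_from_traits(species_traits(1, 1, "A"))
  sim1 <- run_serial_dilution(pool1, matrix(1, 100, 1), 100)
  tau1 <- time_on_preferences(sim1)
  expect_equal(unname(tau1[1]), mean(tail(sim1$cycle_lengths, 20)),
               tolerance = 1e-9)

  # constant equal supply: niches nearly simultaneous, growth mostly rank 1
  set.seed(52)
  pool <- sample_pool(3, 100)
  sim0 <- run_serial_dilution(pool, constant_supply(3, 2000), 2000)
  tau0 <- time_on_preferences(sim0)
  expect_gt(tau0[1], 5 * (tau0[2] + tau0[3]))

  # single random resource each cycle: equal time on each rank
  sim471 <- run_serial_dilution(pool, single_resource_supply(3, 2000), 2000)
  tau471 <- time_on_preferences(sim471)
  expect_lt(diff(range(tau471)) / mean(tau471), 0.15)
})

test_that("optimal allocation maximises growth under the L2 constraint", {
  expect_equal(optimal_allocation(c(2, 0, 0)), c(1, 0, 0))
  expect_equal(optimal_allocation(c(1, 1, 1)), rep(1 / sqrt(3), 3))
  # against a numerical spherical maximisation oracle
  set.seed(53)
  for (case in 1:5) {
    tau <- runif(3)
    g <- optimal_allocation(tau)
    obj <- function(ang) { # spherical coordinates on the positive octant
      v <- c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]),
             sin(ang[1]))
      -sum(v * tau)
    }
    opt <- optim(c(pi / 4, pi / 4), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    v <- c(cos(opt$par[1]) * cos(opt$par[2]),
           cos(opt$par[1]) * sin(opt$par[2]), sin(opt$par[1]))
    expect_equal(g, v, tolerance = 1e-5)
    expect_equal(sum(g^2), 1, tolerance = 1e-12)
  }
  expect_equal(optimal_allocation(c(0.5, 0.3, 0.2)),
               c(0.5, 0.3, 0.2) / sqrt(0.38), tolerance = 1e-12)
  expect_error(optimal_allocation(c(0, 0)), "zero")
})

test_that("the optimal strategy set covers every preference order", {
  st <- optimal_strategy_set(c(0.5, 0.3, 0.2))
  expect_identical(nrow(st$growth_rates), 6L)
  expect_true(all(abs(rowSums(st$growth_rates^2) - 1) < 1e-12))
  expect_identical(nrow(unique(st$preferences)), 6L)
  # rank-1 rate lands on the preferred resource of each order
  for (r in 1:6)
    expect_equal(st$growth_rates[r, st$preferences[r, 1]],
                 st$allocation[1])
  st4 <- optimal_strategy_set(c(4, 3, 2, 1))
  expect_identical(nrow(st4$growth_rates), 24L)
})

test_that("simplex coordinates anchor corners and centroid", {
  cen <- simplex_coordinates(c(1, 1, 1) / 3)
  expect_equal(as.numeric(cen), c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  expect_equal(as.numeric(simplex_coordinates(c(1, 0, 0))), c(0, 0))
  # squared-growth mode: equal investment maps to the centroid too
  cen2 <- simplex_coordinates(rep(1 / sqrt(3), 3), mode = "squared-growth")
  expect_equal(as.numeric(cen2), c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  expect_equal(as.numeric(simplex_coordinates(c(1, 0, 0), "squared-growth")),
               c(0, 0))
  expect_error(simplex_coordinates(c(1, 1)), "3 components")
})

test_that("strategy distances vanish at strategies and respect symmetry", {
  st <- optimal_strategy_set(c(0.6, 0.3, 0.1))
  d0 <- survivor_strategy_distance(st$growth_rates, st)
  expect_true(all(d0 < 1e-12))
  set.seed(54)
  g <- sample_growth_rates(3, 10)
  d <- survivor_strategy_distance(g, st)
  # relabeling resources consistently leaves distances unchanged
  perm <- c(2, 3, 1)
  st_p <- st$growth_rates[, perm]
  d_p <- survivor_strategy_distance(g[, perm], st_p)
  expect_equal(d, d_p, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(survivor_strategy_distance(g[0, , drop = FALSE], st),
               "no survivors")
})
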