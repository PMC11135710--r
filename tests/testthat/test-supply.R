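test_that("fluctuation magnitude matches its analytic reference points", {
  # equal supply: zero fluctuation
  expect_equal(fluctuation_magnitude(constant_supply(3, 100)), 0)
  # permutations of (1,0,0): sqrt(2/9), regardless of which corner
  corners <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(fluctuation_magnitude(corners), sqrt(2 / 9))
  expect_equal(sigma_rs_single_resource(3), sqrt(2 / 9))
  expect_equal(sigma_rs_uniform(3), sqrt(1 / 18))
  # uniform simplex draws: sqrt(1/18) within Monte-Carlo error
  set.seed(21)
  expect_equal(fluctuation_magnitude(sample_uniform_simplex(3, 1e5)),
               sqrt(1 / 18), tolerance = 0.01)
})

test_that("uniform simplex sampler is symmetric and on the simplex", {
  set.seed(22)
  s <- sample_uniform_simplex(3, 1e5)
  expect_true(all(abs(rowSums(s) - 1) < 1e-12))
  expect_true(all(s >= 0))
  expect_true(all(abs(colMeans(s) - 1 / 3) < 0.003))
  s7 <- sample_uniform_simplex(7, 100)
  expect_true(all(s7 >= 0))
  expect_true(all(abs(rowSums(s7) - 1) < 1e-12))
})

test_that("single-resource supply picks each resource uniformly", {
  set.seed(23)
  s <- single_resource_supply(3, 3e4)
  expect_true(all(rowSums(s) == 1))
  expect_true(all(rowSums(s > 0) == 1))
  expect_true(all(abs(colMeans(s) - 1 / 3) < 0.01))
  expect_equal(fluctuation_magnitude(s), sqrt(2 / 9), tolerance = 1e-12)
})

test_that("seasonal generator reproduces the printed supply tables to 3 decimals", {
  tab <- read.csv(system.file("extdata", "seasonal_supply_table.csv",
                              package = "diauxie"))
  for (P in c(3, 6, 12)) {
    rows <- tab[tab$period == P, ]
    gen <- seasonal_supply(P, rows$cycle)
    expect_lt(max(abs(gen - as.matrix(rows[, c("s1", "s2", "s3")]))), 5e-4)
  }
  # every generated cycle sums to exactly 1 and stays nonnegative
  s <- seasonal_supply(12, 1:36)
  expect_true(all(abs(rowSums(s) - 1) < 1e-12))
  expect_true(all(s >= 0))
  expect_error(seasonal_supply(3, amplitude = 0.4), "amplitude")
})

test_that("shape-parameter calibration is monotone with the right limits", {
  # small positive v: clipping negligible, sigma^2 = 2v/3
  expect_equal(sigma_rs_for_shape(1e-4), sqrt(2e-4 / 3), tolerance = 0.01)
  # v -> +Inf: uniform limit
  expect_equal(sigma_rs_for_shape(50), sigma_rs_uniform(3), tolerance = 0.005)
  expect_equal(sigma_rs_for_shape(Inf), sigma_rs_uniform(3))
  # small negative v: corner-concentrated, approaching 0.471
  expect_gt(sigma_rs_for_shape(-2e-4), 0.46)
  # monotone on each branch
  vpos <- c(1e-3, 1e-2, 1e-1, 1, 10)
  expect_true(all(diff(sapply(vpos, sigma_rs_for_shape)) > 0))
  expect_true(all(diff(sapply(-rev(vpos), sigma_rs_for_shape)) > 0))
})

test_that("supply sampler hits target magnitudes within 1 percent", {
  set.seed(24)
  for (target in c(0.03, 0.09, 0.15, 0.21, 0.27, 0.35, 0.43)) {
    s <- supply_sampler(target)(1e5)
    expect_true(all(s >= 0))
    expect_lt(max(abs(rowSums(s) - 1)), 1e-12)
    expect_lt(abs(fluctuation_magnitude(s) - target) / target, 0.01)
    # exchangeable in resource indices
    expect_true(all(abs(colMeans(s) - 1 / 3) < 0.01))
  }
})

test_that("sampler endpoints are handled exactly", {
  set.seed(25)
  expect_equal(supply_sampler(0)(5), constant_supply(3, 5))
  s <- supply_sampler(sqrt(2 / 9))(100)
  expect_true(all(rowSums(s > 0) == 1))
  expect_error(supply_sampler(0.5), "sigma_rs")
  expect_error(supply_sampler(-0.1), "sigma_rs")
  expect_error(supply_sampler(0.15, n_resources = 4), "3 resources")
  # uniform point: indistinguishable from the flat simplex distribution
  u <- supply_sampler(sigma_rs_uniform(3))(2000)
  ref <- sample_uniform_simplex(3, 2000)
  expect_gt(ks.test(u[, 1], ref[, 1])$p.value, 0.01)
})

test_that("normal-draw and uniform-rejection samplers agree at the crossover", {
  set.seed(26)
  v <- fluctuation_shape(0.21)
  a <- diauxie:::sampler_normal(v)(8000)
  b <- diauxie:::sampler_rejection(v)(8000)
  # same density: compare one coordinate and the radial distance
  expect_gt(ks.test(a[, 1], b[, 1])$p.value, 0.01)
  expect_gt(ks.test(rowSums((a - 1 / 3)^2), rowSums((b - 1 / 3)^2))$p.value,
            0.01)
})

test_that("supply resolution validates schedules", {
  expect_error(resolve_supply(c(0.5, 0.6), 5, 2), "sum to 1")
  expect_error(resolve_supply(c(0.5, 0.5), 5, 3), "resources")
  expect_error(resolve_supply(matrix(0.5, 2, 2), 5, 2), "shorter")
  s <- resolve_supply(c(0.3, 0.7), 4, 2)
  expect_equal(dim(s), c(4L, 2L))
})
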