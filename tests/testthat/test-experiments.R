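test_that("the survivor protocol recovers unambiguous winners", {
  # one resource, one clear fastest grower
  pool <- new_species_pool(matrix(c(1.0, 0.7, 0.4), 3, 1),
                           matrix(1L, 3, 1),
                           species_id = c("fast", "mid", "slow"))
  set.seed(61)
  rep <- survivor_protocol(pool, matrix(1, 500, 1), n_cycles = 500,
                           n_primary = 2, n_headstart = 2,
                           min_survivals = 2)
  expect_identical(rep$survivors, "fast")
  expect_false(rep$ce_violation)

  # mirror-symmetric pair: both survive every repetition
  pool2 <- generate_fixtures("mirror-pair")
  rep2 <- survivor_protocol(pool2, c(0.5, 0.5), n_cycles = 500,
                            n_primary = 1, n_headstart = 2,
                            min_survivals = 2)
  expect_identical(rep2$survivors, c("A", "B"))
  expect_true(all(rep2$headstart_counts == 2))
})

test_that("the survivor protocol is idempotent on its own survivors", {
  set.seed(62)
  pool <- sample_pool(3, 60)
  sampler <- supply_sampler(0.15)
  rep1 <- survivor_protocol(pool, sampler, n_cycles = 3000)
  reduced <- pool[rep1$survivor_idx]
  rep2 <- survivor_protocol(reduced, sampler, n_cycles = 3000)
  expect_setequal(rep2$survivors, rep1$survivors)
})

test_that("diversity-law fits recover exact generating parameters", {
  x <- rep(2:7, each = 3)
  fit_m <- fit_diversity_law(data.frame(n_resources = x,
                                        n_survivors = 0.44 * x^2.14))
  expect_equal(unname(coef(fit_m, "monomial")), c(0.44, 2.14),
               tolerance = 1e-6)
  expect_identical(fit_m$best, "monomial")
  expect_equal(fit_m$fits$monomial$r_squared, 1, tolerance = 1e-9)

  fit_e <- fit_diversity_law(data.frame(n_resources = x,
                                        n_survivors = 1.6 * exp(0.41 * x)))
  expect_equal(unname(coef(fit_e, "exponential")), c(1.6, 0.41),
               tolerance = 1e-6)
  expect_identical(fit_e$best, "exponential")

  fit_l <- suppressWarnings( # lm warns on an exactly collinear fit
    fit_diversity_law(data.frame(n_resources = x, n_survivors = 2 + 3 * x)))
  expect_equal(unname(coef(fit_l, "linear")), c(2, 3), tolerance = 1e-8)
  expect_identical(fit_l$best, "linear")

  # prediction and F-tests behave
  expect_equal(unname(predict(fit_m, 13)), 0.44 * 13^2.14, tolerance = 1e-5)
  p <- fit_m$f_tests["monomial", "linear"]
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  expect_error(fit_diversity_law(data.frame(n_resources = c(2, 2, 3),
                                            n_survivors = 1:3)), "distinct")
})

test_that("noisy monomial data prefer the monomial family", {
  set.seed(63)
  x <- rep(2:7, each = 4)
  y <- 0.44 * x^2.14 * exp(rnorm(length(x), 0, 0.08))
  fit <- fit_diversity_law(data.frame(n_resources = x, n_survivors = y))
  expect_gt(fit$fits$monomial$r_squared, fit$fits$linear$r_squared)
  expect_equal(unname(coef(fit, "monomial")[2]), 2.14, tolerance = 0.15)
})

test_that("dynamics classification distinguishes fixed points, cycles, and noise", {
  fake_sim <- function(f) {
    structure(list(recorded_cycles = seq_len(nrow(f)), fractions = f,
                   survivors = seq_len(ncol(f))), class = "diauxie_sim")
  }
  const <- fake_sim(matrix(c(0.6, 0.4), 400, 2, byrow = TRUE))
  expect_identical(classify_dynamics(const, window = 300)$type,
                   "fixed_point")
  alt <- fake_sim(matrix(rep(c(0.7, 0.3, 0.3, 0.7), 200), ncol = 2,
                         byrow = TRUE))
  cls <- classify_dynamics(alt, window = 300)
  expect_identical(cls$type, "periodic")
  expect_identical(cls$period, 2L)
  set.seed(64)
  noise <- fake_sim(cbind(runif(400, 0.2, 0.8), runif(400, 0.2, 0.8)))
  expect_identical(classify_dynamics(noise, window = 300)$type, "aperiodic")
})

test_that("three specialists each dominate one season", {
  pool <- generate_fixtures("three-specialists")
  res <- seasonal_assembly(3, list(pool), n_cycles = 600)
  expect_identical(res$n_survivors, 3L)
  expect_equal(res$mean_survivors, 3)
})

test_that("scaled sweeps show fluctuation-enabled coexistence", {
  set.seed(65)
  pools <- lapply(1:4, function(i) sample_pool(3, 120))
  sw <- ce_violation_sweep(pools, c(0, 0.15), n_cycles = 3000)
  expect_identical(dim(sw$counts), c(4L, 2L))
  # violations never decrease from zero fluctuation, where they are (near) zero
  expect_gte(sw$summary$violation_fraction[2],
             sw$summary$violation_fraction[1])
  expect_true(all(sw$counts >= 1))
})
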