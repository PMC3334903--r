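test_that("design arithmetic matches the closed forms", {
  d <- pm_design(strains = 4, biological_replicates = 2,
                 technical_replicates = 10)
  expect_identical(n_curves(d), 7680L)
  expect_identical(nrow(build_design(d)), 7680L)

  d3 <- design_cultivation_time()
  expect_identical(n_curves(d3), 3264L)   # 3072 + 192
  expect_identical(n_plates(d3), 34L)
  expect_identical(n_replicate_groups(d3), 864L)
  expect_identical(nrow(build_design(d3)), 3264L)

  expect_identical(n_curves(pm_design(strains = 1)), 96L)
  expect_error(pm_design(strains = 1, wells_per_plate = 0), "zero wells")
  expect_error(pm_design(strains = 1, technical_replicates = 0), "positive")
})

test_that("simulated curves follow their shape specs", {
  tg <- seq(0, 91, 0.5)
  flat <- simulate_curve(shape_spec("flat", baseline = 20, noise_sd = 0),
                         times = tg)
  expect_equal(flat$values, rep(20, length(tg)))

  # analytic identity of the logistic form at t = lambda
  lg <- simulate_curve(shape_spec("logistic", A = 300, mu = 20, lambda = 10,
                                  noise_sd = 0), times = tg)
  expect_equal(lg$values[tg == 10], 300 / (1 + exp(2)), tolerance = 1e-12)

  # biphasic: interim plateau between the two ascents
  bi <- shape_spec("biphasic", A = 150, mu = 40, lambda = 5,
                   A2 = 100, mu2 = 8, lambda2 = 50, noise_sd = 0)
  y <- shape_value(bi, tg)
  expect_equal(y[tg == 30], 150, tolerance = 0.02)     # interim plateau
  expect_equal(max(y), 250, tolerance = 0.02)          # final plateau

  expect_error(simulate_curve(bi, times = c(0, 1, 1, 2)),
               "strictly increasing")
  expect_error(shape_spec("logistic", A = 500), "cap")
})

test_that("simulation is seed-deterministic and respects the instrument range", {
  sp <- shape_spec("gompertz", A = 390, mu = 25, lambda = 5, noise_sd = 20,
                   spike = TRUE, dip = TRUE)
  a <- simulate_curve(sp, seed = 7)
  b <- simulate_curve(sp, seed = 7)
  c <- simulate_curve(sp, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_true(all(a$values >= 0 & a$values <= 400))
})

test_that("experiments honour design, policy and seed", {
  d <- pm_design(strains = c("x", "y"), technical_replicates = 2)
  pl <- simulate_experiment(d, seed = 5)
  expect_length(pl, 4)
  expect_true(all(vapply(pl, function(p) length(p$curves), 1L) == 96L))
  pl2 <- simulate_experiment(d, seed = 5)
  expect_equal(vapply(pl, function(p) p$curves[["C03"]]$values[10], 1),
               vapply(pl2, function(p) p$curves[["C03"]]$values[10], 1))

  # noise-free policy: technical replicates are identical
  pol <- function(strain, well) shape_spec("logistic", noise_sd = 0)
  pq <- simulate_experiment(d, policy = pol, seed = 1)
  expect_identical(pq[[1]]$curves[["B02"]]$values,
                   pq[[2]]$curves[["B02"]]$values)

  # replicate curves share the true shape under the default policy
  shapes <- default_shape_policy(seed = 5)
  expect_identical(shapes("x", "D04")$family, shapes("x", "D04")$family)
  expect_error(simulate_experiment(d, policy = list(), seed = 1),
               "no shape")
})

test_that("all generated values stay within [0, 400] across a plate", {
  pl <- simulate_experiment(pm_design(strains = "s"), seed = 13)[[1]]
  rng <- range(vapply(pl$curves, function(cv) range(cv$values),
                      numeric(2)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 400)
})
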