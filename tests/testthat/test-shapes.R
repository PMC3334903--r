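test_that("reaction calls apply the strict positivity threshold", {
  expect_identical(call_reaction(c(150, 100, 0, NA)),
                   c("positive", "negative", "negative", NA))
  expect_identical(call_reaction(100.0001), "positive")
  expect_identical(call_reaction(50, threshold = 40), "positive")
})

test_that("lambda truncation is the one-line clamp and is idempotent", {
  expect_equal(truncate_lambda(c(-500, -2, 5, 10)), c(-10, -2, 5, 10))
  x <- c(-3, 0, 4)
  expect_equal(truncate_lambda(x), x)           # all within [-M, M]
  set.seed(6)
  for (i in 1:30) {
    v <- stats::rnorm(20, 0, 50)
    M <- max(v)
    want <- ifelse(v < -M, -M, v)               # independent one-liner
    got <- truncate_lambda(v)
    expect_equal(got, want)
    expect_equal(truncate_lambda(got), got)     # idempotent
  }
  expect_error(truncate_lambda(c(NA_real_, NA_real_)), "missing")
})

test_that("k = 1 archetype is the data mean with the centered SS as RSS", {
  set.seed(8)
  X <- matrix(rnorm(200, 5, 2), 50, 4,
              dimnames = list(NULL, c("lambda", "mu", "A", "AUC")))
  fit <- fit_archetypes(X, k = 1, seed = 3)
  expect_equal(drop(fit$archetypes), colMeans(X), tolerance = 1e-6)
  Xs <- scale(X)
  expect_equal(fit$rss, sum(Xs^2), tolerance = 1e-4)
})

test_that("planted simplex vertices are recovered and elbow-selected", {
  set.seed(12)
  V <- rbind(c(0, 0, 0, 0), c(10, 0, 5, 0), c(5, 8, 0, 3))
  X <- V[sample(1:3, 300, replace = TRUE), ] +
    matrix(rnorm(1200, 0, 0.05), 300, 4)
  sc <- suppressWarnings(
    step_archetypes_elbow(X, k_range = 1:6, restarts = 3, seed = 2,
                          max_iter = 60))
  expect_identical(sc$k_selected, 3L)
  Z <- sc$models[["3"]]$archetypes
  # match each vertex to its nearest recovered archetype
  for (i in 1:3) {
    d <- sqrt(rowSums((Z - matrix(V[i, ], 3, 4, byrow = TRUE))^2))
    expect_lt(min(d), 0.15)
  }
  expect_lt(sc$models[["3"]]$rss, sc$models[["1"]]$rss / 100)
})

test_that("coefficients live on the simplex and the RSS trace descends", {
  set.seed(19)
  X <- matrix(rnorm(160), 40, 4)
  for (k in c(2, 4)) {
    fit <- fit_archetypes(X, k = k, seed = k)
    expect_true(all(fit$coefficients >= -1e-8))
    expect_lt(max(abs(rowSums(fit$coefficients) - 1)), 1e-8)
    expect_true(all(diff(fit$rss_trace) <= 1e-10))
  }
  expect_error(fit_archetypes(X, k = 50), "k <= nrow")
})

test_that("unstructured data yield early, dominant drops", {
  set.seed(33)
  X <- matrix(rnorm(400), 100, 4)
  sc <- suppressWarnings(
    step_archetypes_elbow(X, k_range = 1:5, restarts = 2, seed = 4,
                          max_iter = 40))
  dr <- sc$drops
  # the early improvement dominates everything after it
  expect_gte(max(dr[1:2]), max(dr[-(1:2)]))
})

test_that("rank correlations match brute-force pair counting", {
  x <- c(1.2, 0.5, 3.3, 2.2, 0.1)
  y <- c(2.0, 1.1, 2.9, 3.8, 0.4)
  tab <- cbind(x = x, y = y)
  sp <- parameter_correlations(tab, "spearman")
  kd <- parameter_correlations(tab, "kendall")
  expect_equal(sp["x", "y"], oracle_spearman(x, y))
  expect_equal(kd["x", "y"], oracle_kendall(x, y))
  expect_equal(diag(sp), c(x = 1, y = 1))
  # monotone invariance
  ey <- exp(x)
  m <- parameter_correlations(cbind(x, ey))
  expect_equal(m[1, 2], 1)
  expect_equal(parameter_correlations(cbind(x, ey), "kendall")[1, 2], 1)
  # constant column: undefined, reported missing
  cc <- parameter_correlations(cbind(x, const = rep(1, 5)))
  expect_true(is.na(cc["x", "const"]))
  expect_error(parameter_correlations(tab[1:2, ]), "3 complete rows")
})
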