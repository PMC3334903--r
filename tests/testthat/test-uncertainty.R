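test_that("bootstrap CIs are seed-reproducible and degenerate on noiseless lines", {
  tg <- default_time_grid()
  line <- pm_curve(tg, 2 * tg)
  ci <- bootstrap_cis(line, "spline", B = 30, seed = 5)
  # every resample refits the same line: numerically zero-width intervals
  w <- with(ci$table, (upper - lower) / pmax(1, abs(estimate)))
  expect_lt(max(w), 1e-6)

  cv <- simulate_curve(shape_spec("logistic", noise_sd = 4), seed = 2)
  a <- bootstrap_cis(cv, "spline", B = 25, seed = 77)
  b <- bootstrap_cis(cv, "spline", B = 25, seed = 77)
  d <- bootstrap_cis(cv, "spline", B = 25, seed = 78)
  expect_identical(a$table, b$table)
  expect_false(identical(a$table, d$table))
  expect_identical(a$level, 0.95)
})

test_that("flat noisy negatives give far broader lag/slope CIs than sigmoids", {
  flat <- simulate_curve(shape_spec("linear_drift", baseline = 10,
                                    drift = 0.15, noise_sd = 4), seed = 31)
  sig <- simulate_curve(shape_spec("logistic", A = 300, mu = 20, lambda = 10,
                                   noise_sd = 4), seed = 32)
  ci_flat <- bootstrap_cis(flat, "spline", B = 40, seed = 1)
  ci_sig <- bootstrap_cis(sig, "spline", B = 40, seed = 1)
  width <- function(ci, p) {
    r <- ci$table[ci$table$parameter == p, ]
    r$upper - r$lower
  }
  expect_gt(width(ci_flat, "lambda"), 5 * width(ci_sig, "lambda"))
  expect_gt(width(ci_flat, "mu") / 0.15, width(ci_sig, "mu") / 20)
})

test_that("CI overlap and minimum expectable difference follow interval arithmetic", {
  r <- ci_overlap(c(1, 2), c(3, 4))
  expect_false(r$overlaps)
  expect_equal(r$min_expected_difference, 1)
  expect_true(ci_overlap(c(1, 3), c(2, 4))$overlaps)
  expect_true(ci_overlap(c(1, 2), c(2, 3))$overlaps)  # closed intervals
  expect_equal(ci_overlap(c(1, 2), c(2, 3))$min_expected_difference, 0)
  r2 <- ci_overlap(c(3, 4), c(1, 2))
  expect_equal(r2$min_expected_difference, -1)        # signed by direction

  # antisymmetry and translation invariance on random interval pairs
  set.seed(11)
  for (i in 1:50) {
    a <- sort(stats::runif(2, -10, 10)); b <- sort(stats::runif(2, -10, 10))
    ab <- ci_overlap(a, b); ba <- ci_overlap(b, a)
    expect_identical(ab$overlaps, ba$overlaps)
    expect_equal(ab$min_expected_difference, -ba$min_expected_difference)
    sh <- ci_overlap(a + 3.7, b + 3.7)
    expect_equal(sh$min_expected_difference, ab$min_expected_difference)
  }

  df_a <- data.frame(parameter = "A", lower = 1, upper = 2, level = 0.95)
  df_b <- data.frame(parameter = "mu", lower = 3, upper = 4, level = 0.95)
  expect_error(ci_overlap(df_a, df_b), "different parameters")
  df_c <- data.frame(parameter = "A", lower = 3, upper = 4, level = 0.9)
  expect_error(ci_overlap(df_a, df_c), "levels")
})

test_that("group-mean CIs average members exactly", {
  one <- data.frame(group = "g1", parameter = "A", estimate = 1.5,
                    lower = 1, upper = 2)
  expect_equal(group_mean_cis(one)[, c("estimate", "lower", "upper")],
               data.frame(estimate = 1.5, lower = 1, upper = 2))

  two <- data.frame(group = "g", parameter = "A", estimate = c(1, 3),
                    lower = c(0, 2), upper = c(2, 4))
  g <- group_mean_cis(two)
  expect_equal(c(g$estimate, g$lower, g$upper), c(2, 1, 3))

  set.seed(4)
  tab <- data.frame(group = sample(letters[1:3], 60, TRUE),
                    parameter = sample(c("A", "mu"), 60, TRUE),
                    estimate = rnorm(60), lower = rnorm(60), upper = rnorm(60))
  got <- group_mean_cis(tab)
  for (i in seq_len(nrow(got))) {
    sel <- tab$group == got$group[i] & tab$parameter == got$parameter[i]
    expect_equal(got$estimate[i], mean(tab$estimate[sel]))
    expect_equal(got$lower[i], mean(tab$lower[sel]))
  }
  expect_error(group_mean_cis(tab[0, ]), "empty")
})

test_that("a single contrast reproduces the classical pooled t interval", {
  set.seed(9)
  v <- c(rnorm(8, 5, 2), rnorm(12, 7, 2))
  g <- rep(c("a", "b"), c(8, 12))
  cmp <- simultaneous_mean_differences(v, g, contr_all_pairs(c("a", "b")),
                                       seed = 1)
  tt <- stats::t.test(v[g == "b"], v[g == "a"], var.equal = TRUE)
  expect_equal(cmp$table$estimate, unname(diff(rev(tt$estimate))),
               tolerance = 1e-10)
  expect_equal(c(cmp$table$lower, cmp$table$upper),
               as.numeric(tt$conf.int), tolerance = 1e-8)
})

test_that("Monte-Carlo simultaneous intervals agree with an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(15)
  v <- rnorm(24, rep(c(0, 1, 3), each = 8), 1.5)
  g <- factor(rep(c("a", "b", "c"), each = 8))
  K <- contr_all_pairs(levels(g))
  cmp <- simultaneous_mean_differences(v, g, K, seed = 2, nmc = 2e5)
  fit <- stats::lm(v ~ g - 1)
  ref <- stats::confint(multcomp::glht(fit, linfct = K %*% diag(3)))
  expect_equal(cmp$table$estimate, unname(ref$confint[, "Estimate"]),
               tolerance = 1e-10)
  expect_equal(cmp$table$lower, unname(ref$confint[, "lwr"]), tolerance = 0.02)
  expect_equal(cmp$table$upper, unname(ref$confint[, "upr"]), tolerance = 0.02)
})

test_that("simultaneous intervals widen over unadjusted ones and validate input", {
  set.seed(21)
  v <- rnorm(30); g <- factor(rep(letters[1:5], each = 6))
  K <- contr_all_pairs(levels(g))
  cmp <- simultaneous_mean_differences(v, g, K, seed = 3)
  expect_gte(cmp$crit, stats::qt(0.975, cmp$df))

  bad <- K; bad[2, 1] <- bad[2, 1] + 0.5
  expect_error(simultaneous_mean_differences(v, g, bad, seed = 1),
               "not summing to zero")
  expect_error(simultaneous_mean_differences(v, g, K * 0, seed = 1),
               "all-zero|not summing")
  expect_error(simultaneous_mean_differences(v[1:6], g[1:6], K, seed = 1),
               "two groups")
})

test_that("contrast helpers span the expected comparisons", {
  K <- contr_all_pairs(c("a", "b", "c"))
  expect_identical(dim(K), c(3L, 3L))
  expect_true(all(abs(rowSums(K)) < 1e-12))
  Kc <- contr_vs_control(c("ctrl", "x", "y"), control = "ctrl")
  expect_identical(rownames(Kc), c("x - ctrl", "y - ctrl"))
  expect_true(all(Kc[, "ctrl"] == -1))
})
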