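# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (plain scans, order statistics,
# pair counting) so that they share no code with the package internals.

# Literal implementation of the instrument's parametric definitions.
oracle_native <- function(times, values) {
  n <- length(values)
  sorted_all <- sort(values)
  max_height <- sorted_all[max(1, ceiling(0.9 * n))]
  pool <- values[seq_len(min(48, n))]
  min_height <- if (length(pool) >= 12) sort(pool)[12] else min(pool)
  mid_height <- (min_height + max_height) / 2

  first_above <- function(th) {
    for (i in seq_len(n)) if (values[i] > th) return(i)
    NA_integer_
  }
  i_mid <- first_above(mid_height)
  i_15 <- first_above(min_height + 0.15 * (max_height - min_height))
  i_85 <- first_above(min_height + 0.85 * (max_height - min_height))

  slope <- NA_real_
  lambda <- NA_real_
  if (!anyNA(c(i_mid, i_15, i_85)) && times[i_85] != times[i_15]) {
    rises <- 0
    if (i_mid - 1 >= i_15)
      for (i in seq(i_15, i_mid - 1)) if (i > i_15)
        rises <- rises + (values[i] - values[i - 1])
    if (i_85 >= i_mid + 1)
      for (i in seq(i_mid + 1, i_85)) if (i > i_mid + 1)
        rises <- rises + (values[i] - values[i - 1])
    slope <- rises / (times[i_85] - times[i_15])
    if (slope != 0)
      lambda <- times[i_mid] - (mid_height - min_height) / slope
    else slope <- NA_real_
  }
  list(MaxHeight = max_height, MinHeight = min_height, MidHeight = mid_height,
       MidTime = if (is.na(i_mid)) NA_real_ else times[i_mid],
       PctTime15 = if (is.na(i_15)) NA_real_ else times[i_15],
       PctTime85 = if (is.na(i_85)) NA_real_ else times[i_85],
       Slope = slope, lambda = lambda,
       A = max_height, AUC = sum(values))
}

# O(n^2) scanner for decreasing runs and single-sample spikes.
oracle_artifacts <- function(y, tol) {
  n <- length(y)
  spikes <- integer()
  for (i in seq_len(n)) {
    if (i > 1 && i < n &&
        y[i] - y[i - 1] > tol && y[i] - y[i + 1] > tol)
      spikes <- c(spikes, i)
  }
  drops <- list()
  i <- 1
  while (i < n) {
    if (y[i + 1] < y[i]) {
      j <- i
      while (j < n && y[j + 1] <= y[j]) j <- j + 1
      if (y[i] - y[j] > tol) drops[[length(drops) + 1]] <- c(i, j, y[i] - y[j])
      i <- j
    } else i <- i + 1
  }
  list(spikes = spikes, drops = drops)
}

# Rank correlations from first principles.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# A random well-formed curve mixing shapes and artifacts, for property tests.
random_test_curve <- function(n = 60, tmax = 30) {
  t <- sort(stats::runif(n, 0, tmax))
  t <- t + seq_len(n) * 1e-6  # guard against ties
  kind <- sample(c("sig", "line", "flat", "noisy"), 1)
  y <- switch(kind,
    sig = 300 / (1 + exp((4 * 15 / 300) * (stats::runif(1, 2, 10) - t) + 2)),
    line = stats::runif(1, 0.5, 5) * t,
    flat = rep(stats::runif(1, 0, 50), n),
    noisy = stats::runif(n, 0, 100))
  y <- pmin(pmax(y + stats::rnorm(n, 0, 5), 0), 400)
  pm_curve(t, y)
}
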