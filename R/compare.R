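#' CI overlap and minimum expectable difference
#'
#' Two confidence intervals for the same parameter at the same level are
#' compared as closed intervals. If they overlap (shared endpoints count as
#' overlap) no difference is detectable and the minimum expectable difference
#' is 0. If they are disjoint, the difference is statistically detectable and
#' the gap between the nearer opposite limits is a lower bound on the
#' underlying mean difference -- signed positive when `b` lies above `a`,
#' negative when below.
#'
#' @param a,b Interval descriptions: either one-row slices of a `pm_ci` table
#'   (with `parameter`, `lower`, `upper`), a `pm_ci` restricted via
#'   `parameter`, or plain numeric vectors `c(lower, upper)`.
#' @param parameter When `a`/`b` are `pm_ci` objects, which parameter to
#'   compare.
#' @return A list with `overlaps` (logical) and `min_expected_difference`
#'   (units; 0 when overlapping).
#' @examples
#' ci_overlap(c(1, 2), c(3, 4))   # disjoint, minimum difference 1
#' ci_overlap(c(1, 3), c(2, 4))   # overlap
#' @export
ci_overlap <- function(a, b, parameter = NULL) {
  pick <- function(x) {
    if (inherits(x, "pm_ci")) {
      if (is.null(parameter))
        stop("give `parameter` when comparing pm_ci objects", call. = FALSE)
      row <- x$table[x$table$parameter == parameter, ]
      if (!nrow(row)) stop("no CI for parameter ", parameter, call. = FALSE)
      list(lo = row$lower, hi = row$upper, parameter = parameter,
           level = x$level)
    } else if (is.data.frame(x)) {
      list(lo = x$lower[1L], hi = x$upper[1L],
           parameter = if ("parameter" %in% names(x)) x$parameter[1L] else NA,
           level = if ("level" %in% names(x)) x$level[1L] else NA)
    } else {
      stopifnot(is.numeric(x), length(x) == 2L)
      list(lo = x[1L], hi = x[2L], parameter = NA, level = NA)
    }
  }
  ia <- pick(a); ib <- pick(b)
  if (!is.na(ia$parameter) && !is.na(ib$parameter) &&
      ia$parameter != ib$parameter)
    stop("intervals are for different parameters: ", ia$parameter, " vs ",
         ib$parameter, call. = FALSE)
  if (!is.na(ia$level) && !is.na(ib$level) && ia$level != ib$level)
    stop("intervals have different confidence levels", call. = FALSE)
  if (anyNA(c(ia$lo, ia$hi, ib$lo, ib$hi)))
    stop("interval limits must not be missing", call. = FALSE)
  if (ia$lo > ia$hi || ib$lo > ib$hi)
    stop("interval limits are reversed", call. = FALSE)
  if (ib$lo > ia$hi)       list(overlaps = FALSE,
                                min_expected_difference = ib$lo - ia$hi)
  else if (ia$lo > ib$hi)  list(overlaps = FALSE,
                                min_expected_difference = ib$hi - ia$lo)
  else                     list(overlaps = TRUE, min_expected_difference = 0)
}

#' Group-mean point estimates and mean CIs
#'
#' Averages per-curve point estimates and per-curve CI limits within groups.
#' This is the quick graphical device for a first look at group behaviour:
#' the averaged limits are not a valid simultaneous testing procedure (use
#' [simultaneous_mean_differences()] for test decisions) but give a useful
#' preliminary display.
#'
#' @param table Data frame with columns `group`, `parameter`, `estimate`,
#'   `lower`, `upper` (e.g. stacked `pm_ci` tables).
#' @return Data frame with one row per (group, parameter): mean estimate and
#'   mean limits, plus the member count `n`.
#' @export
group_mean_cis <- function(table) {
  need <- c("group", "parameter", "estimate", "lower", "upper")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(table)) stop("empty table", call. = FALSE)
  agg <- function(v) stats::aggregate(
    table[[v]], by = list(group = table$group, parameter = table$parameter),
    FUN = mean)$x
  cnt <- stats::aggregate(table$estimate,
                          by = list(group = table$group,
                                    parameter = table$parameter),
                          FUN = length)
  data.frame(group = cnt$group, parameter = cnt$parameter,
             estimate = agg("estimate"), lower = agg("lower"),
             upper = agg("upper"), n = cnt$x, stringsAsFactors = FALSE)
}

#' Contrast matrices for common comparison families
#'
#' @param levels Character vector of group names.
#' @param control Name of the control group (`contr_vs_control`).
#' @return A contrast matrix with one row per comparison and one named column
#'   per group; every row sums to zero.
#' @export
contr_all_pairs <- function(levels) {
  levels <- as.character(levels)
  cmb <- utils::combn(levels, 2L)
  K <- matrix(0, ncol(cmb), length(levels),
              dimnames = list(paste(cmb[2L, ], "-", cmb[1L, ]), levels))
  for (i in seq_len(ncol(cmb))) {
    K[i, cmb[1L, i]] <- -1
    K[i, cmb[2L, i]] <- 1
  }
  K
}

#' @rdname contr_all_pairs
#' @export
contr_vs_control <- function(levels, control = levels[1L]) {
  levels <- as.character(levels)
  stopifnot(control %in% levels)
  others <- setdiff(levels, control)
  K <- matrix(0, length(others), length(levels),
              dimnames = list(paste(others, "-", control), levels))
  for (i in seq_along(others)) {
    K[i, others[i]] <- 1
    K[i, control] <- -1
  }
  K
}

#' Simultaneous CIs for user-defined differences of group means
#'
#' Fits a one-way layout to per-curve parameter point estimates (one value
#' per curve) and computes simultaneous confidence intervals for a
#' user-defined set of contrasts of the group means, using the pooled error
#' variance and the max-|t| critical value of the joint multivariate t
#' distribution implied by the contrasts' correlation structure. The critical
#' value is obtained by seeded Monte Carlo (default 1e5 draws); if the
#' correlation matrix is degenerate a Bonferroni-adjusted t quantile is used
#' instead. An interval not containing 0 indicates a statistically detectable
#' difference between the corresponding group means.
#'
#' @param values Numeric vector of per-curve point estimates.
#' @param groups Factor (or coercible) of group membership, same length.
#' @param contrasts Contrast matrix: one row per comparison, one column per
#'   group level (named, or in `levels(groups)` order); rows must sum to 0.
#'   See [contr_all_pairs()] / [contr_vs_control()].
#' @param level Simultaneous confidence level.
#' @param seed Integer seed for the Monte-Carlo critical value.
#' @param nmc Number of Monte-Carlo draws.
#' @return An object of class `pm_comparison`: `table` (contrast, estimate,
#'   lower, upper, excludes_zero), `crit`, `df`, `level`, `seed`.
#' @examples
#' set.seed(3)
#' v <- c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 4))
#' g <- rep(c("a", "b", "c"), each = 5)
#' simultaneous_mean_differences(v, g, contr_all_pairs(unique(g)), seed = 1)
#' @export
simultaneous_mean_differences <- function(values, groups, contrasts,
                                          level = 0.95, seed = 1L,
                                          nmc = 1e5) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  nj <- table(groups)
  if (all(nj < 2L))
    stop("at least one group needs >= 2 members for variance estimation",
         call. = FALSE)
  K <- as.matrix(contrasts)
  if (!is.null(colnames(K))) {
    if (!all(lev %in% colnames(K)))
      stop("contrast columns do not cover all groups", call. = FALSE)
    K <- K[, lev, drop = FALSE]
  } else if (ncol(K) != length(lev)) {
    stop("contrast matrix must have one column per group", call. = FALSE)
  }
  bad <- which(abs(rowSums(K)) > 1e-8)
  if (length(bad))
    stop("contrast row(s) not summing to zero: ",
         paste(if (is.null(rownames(K))) bad else rownames(K)[bad],
               collapse = ", "), call. = FALSE)
  zero <- which(apply(K, 1L, function(r) all(r == 0)))
  if (length(zero))
    stop("degenerate (all-zero) contrast row: ",
         paste(if (is.null(rownames(K))) zero else rownames(K)[zero],
               collapse = ", "), call. = FALSE)

  means <- tapply(values, groups, mean)
  N <- length(values); G <- length(lev)
  df <- N - G
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)
  s2 <- sum(tapply(values, groups,
                   function(v) sum((v - mean(v))^2))) / df
  est <- drop(K %*% means)
  V <- K %*% diag(1 / as.numeric(nj), G) %*% t(K)  # x s2
  se <- sqrt(s2 * diag(V))
  R <- stats::cov2cor(V)

  q <- nrow(K)
  crit <- if (any(!is.finite(R))) {
    stats::qt(1 - (1 - level) / (2 * q), df)  # Bonferroni fallback
  } else if (q == 1L) {
    stats::qt((1 + level) / 2, df)
  } else {
    .with_seed(seed, {
      ev <- eigen(R, symmetric = TRUE)
      rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
      Z <- matrix(stats::rnorm(nmc * q), nmc, q) %*% t(rot)
      W <- sqrt(stats::rchisq(nmc, df) / df)
      stats::quantile(apply(abs(Z), 1L, max) / W, level, names = FALSE)
    })
  }
  tab <- data.frame(
    contrast = if (is.null(rownames(K))) paste0("C", seq_len(q)) else rownames(K),
    estimate = est, lower = est - crit * se, upper = est + crit * se,
    stringsAsFactors = FALSE)
  tab$excludes_zero <- tab$lower > 0 | tab$upper < 0
  structure(list(table = tab, crit = crit, df = df, level = level,
                 seed = seed, s2 = s2, means = means, n = as.numeric(nj)),
            class = "pm_comparison")
}

#' @export
print.pm_comparison <- function(x, ...) {
  cat(sprintf("<pm_comparison> simultaneous %d%% CIs, df=%d, crit=%.3f\n",
              round(100 * x$level), x$df, x$crit))
  print(x$table, row.names = FALSE)
  invisible(x)
}
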