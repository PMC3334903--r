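#' Archetypal analysis of curve-parameter tables
#'
#' Archetypes are extreme, interpretable points in parameter space such that
#' every observation is approximately a convex combination of them. For data
#' matrix X (n x m) and k archetypes the model is `X ~ C Z` with the rows of
#' the coefficient matrix C on the simplex (non-negative, summing to 1) and
#' each archetype itself a convex combination of data rows, `Z = B X` with
#' the rows of B on the simplex. The residual sum of squares
#' `RSS = ||X - C Z||_F^2` is minimised by alternating convex least squares:
#' coefficients for given archetypes, then archetypes for given
#' coefficients, each step solving small non-negative least-squares problems
#' with a sum-to-one penalty row. Candidate archetype updates that would
#' increase the RSS are rejected, so the RSS trace is non-increasing by
#' construction.
#'
#' Columns are standardised to zero mean / unit variance before fitting
#' (curve parameters live on very different scales) and archetypes are
#' reported back in original units.
#'
#' @param X Numeric matrix or data frame, rows = curves (or groups),
#'   columns = parameters. Rows with missing entries are dropped (count kept
#'   in the result).
#' @param k Number of archetypes, `1 <= k <= nrow(X)`.
#' @param max_iter Iteration cap of the alternating minimisation.
#' @param tol Relative RSS-change convergence tolerance.
#' @param seed Optional integer seed for the random simplex initialisation.
#' @param standardize Standardise columns before fitting.
#' @return An object of class `pm_archetypes`: `archetypes` (k x m, original
#'   units), `coefficients` (n x k simplex rows), `rss`, `rss_trace`,
#'   `converged`, `k`, `n_dropped`, `seed`.
#' @examples
#' X <- rbind(matrix(rnorm(60, 0, .05), 30), matrix(rnorm(60, 3, .05), 30))
#' fit_archetypes(X, k = 2, seed = 1)$archetypes
#' @export
fit_archetypes <- function(X, k, max_iter = 100L, tol = 1e-6, seed = NULL,
                           standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(X)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  n <- nrow(X); m <- ncol(X)
  if (k < 1L || k > n) stop("need 1 <= k <= nrow(X)", call. = FALSE)

  ctr <- if (standardize) colMeans(X) else rep(0, m)
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, m)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  M <- 200 * max(1, abs(Xs))  # sum-to-one penalty weight
  res <- .with_seed(seed, .aa_core(Xs, k, max_iter, tol, M))

  Z <- sweep(sweep(res$Z, 2L, scl, "*"), 2L, ctr, "+")
  colnames(Z) <- colnames(X)
  structure(list(archetypes = Z, coefficients = res$C, rss = res$rss,
                 rss_trace = res$trace, converged = res$converged, k = k,
                 n_dropped = n_dropped, seed = seed,
                 center = ctr, scale = scl),
            class = "pm_archetypes")
}

# Non-negative least squares min ||Ax - b|| given G = A'A, d = A'b
# (Lawson-Hanson active set). Small k only.
.nnls_gram <- function(G, d, tol = 1e-10) {
  k <- length(d)
  x <- numeric(k)
  P <- logical(k)
  w <- d
  it <- 0L
  while (any(!P & w > tol * max(1, max(abs(d)))) && it < 30L * k) {
    it <- it + 1L
    j <- which.max(ifelse(P, -Inf, w))
    P[j] <- TRUE
    repeat {
      s <- numeric(k)
      GP <- G[P, P, drop = FALSE]
      s[P] <- solve(GP + 1e-12 * max(diag(GP)) * diag(sum(P)), d[P])
      if (all(s[P] > tol)) break
      idx <- which(P & s <= tol)
      alpha <- min(x[idx] / (x[idx] - s[idx]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- d - drop(G %*% x)
  }
  pmax(x, 0)
}

# Simplex-constrained coefficient rows for fixed archetypes: per data row,
# NNLS on the penalty-augmented system; Gram matrix shared by all rows.
.aa_coef <- function(Xs, Z, M) {
  k <- nrow(Z)
  G <- Z %*% t(Z) + M^2
  D <- Xs %*% t(Z) + M^2   # n x k
  C <- t(apply(D, 1L, function(d) .nnls_gram(G, d)))
  if (k == 1L) C <- matrix(C, ncol = 1L)
  sw <- rowSums(C)
  sw[sw == 0] <- 1
  C / sw  # exact simplex normalisation on top of the penalty solution
}

.aa_core <- function(Xs, k, max_iter, tol, M) {
  n <- nrow(Xs)
  # random simplex rows as initial coefficients
  C <- matrix(stats::rexp(n * k), n, k)
  C <- C / rowSums(C)
  Z <- .aa_update_Z(Xs, C, M)
  C <- .aa_coef(Xs, Z, M)
  rss <- sum((Xs - C %*% Z)^2)
  trace <- rss
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Z_new <- .aa_update_Z(Xs, C, M)
    C_new <- .aa_coef(Xs, Z_new, M)
    rss_new <- sum((Xs - C_new %*% Z_new)^2)
    if (rss_new > rss) { converged <- TRUE; break }  # reject uphill step
    improve <- (rss - rss_new) / max(rss, .Machine$double.eps)
    Z <- Z_new; C <- C_new; rss <- rss_new
    trace <- c(trace, rss)
    if (improve < tol) { converged <- TRUE; break }
  }
  list(Z = Z, C = C, rss = rss, trace = trace, converged = converged)
}

# Archetype update: unconstrained solve for Z given C, then projection of
# each archetype into the convex hull of the data rows (B rows on simplex).
.aa_update_Z <- function(Xs, C, M) {
  k <- ncol(C)
  G <- crossprod(C)
  Zt <- tryCatch(solve(G + 1e-10 * diag(k), crossprod(C, Xs)),
                 error = function(e) matrix(colMeans(Xs), k, ncol(Xs),
                                            byrow = TRUE))
  A <- rbind(t(Xs), M)          # (m+1) x n
  Z <- t(vapply(seq_len(k), function(j) {
    b <- tryCatch(pracma::lsqnonneg(A, c(Zt[j, ], M))$x,
                  error = function(e) NULL)
    if (is.null(b)) {
      # degenerate active set: fall back to the nearest data row (itself a
      # valid convex combination); the RSS guard rejects bad updates anyway
      i0 <- which.min(rowSums(sweep(Xs, 2L, Zt[j, ])^2))
      b <- numeric(nrow(Xs)); b[i0] <- 1
    }
    if (sum(b) > 0) b <- b / sum(b)
    drop(crossprod(b, Xs))
  }, numeric(ncol(Xs))))
  if (ncol(Xs) == 1L) Z <- matrix(Z, nrow = k)
  Z
}

#' @export
print.pm_archetypes <- function(x, ...) {
  cat(sprintf("<pm_archetypes> k=%d, RSS=%.4g, %s after %d iterations\n",
              x$k, x$rss, if (x$converged) "converged" else "iteration cap",
              length(x$rss_trace)))
  print(round(x$archetypes, 4))
  invisible(x)
}

#' Stepwise archetype fits with elbow selection of k
#'
#' Fits archetypes for each k in `k_range` with several random restarts per
#' k, keeping the best (lowest-RSS) fit. The number of shape classes is
#' picked by the elbow criterion on the scree of best RSS values: the
#' optimal k is the one whose RSS improvement over k-1 is largest compared
#' with the subsequent improvement, i.e. k maximising
#' `drop(k) - drop(k+1)` where `drop(k) = RSS(k-1) - RSS(k)`; ties go to the
#' smaller k. A non-monotone best-RSS sequence (a restart failure) triggers a
#' warning but selection still proceeds on the observed drops.
#'
#' @param X As in [fit_archetypes()].
#' @param k_range Candidate numbers of archetypes.
#' @param restarts Random restarts per k.
#' @param seed Integer seed; restart seeds are derived deterministically.
#' @param ... Passed to [fit_archetypes()].
#' @return An object of class `pm_archetype_scree`: `models` (best fit per
#'   k), `scree` (data frame k, rss), `drops`, `k_selected`.
#' @export
step_archetypes_elbow <- function(X, k_range = 1:10, restarts = 5L, seed = 1L,
                                  ...) {
  k_range <- sort(unique(as.integer(k_range)))
  models <- vector("list", length(k_range))
  names(models) <- as.character(k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    best <- NULL
    for (r in seq_len(restarts)) {
      sd_r <- (as.numeric(seed) * 1009 + k * 101 + r) %% 2147483647
      fit <- fit_archetypes(X, k, seed = sd_r, ...)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
    models[[i]] <- best
  }
  rss <- vapply(models, function(mod) mod$rss, 1)
  if (any(diff(rss) > 1e-8))
    warning("best RSS not non-increasing in k; consider more restarts")
  drops <- -diff(rss)                      # drop(k) for k_range[-1]
  k_selected <- if (length(drops) >= 2L) {
    falloff <- drops[-length(drops)] - drops[-1L]
    k_range[-1L][which.max(falloff)]       # ties: which.max takes first
  } else k_range[length(k_range)]
  structure(list(models = models,
                 scree = data.frame(k = k_range, rss = rss),
                 drops = stats::setNames(drops, k_range[-1L]),
                 k_selected = k_selected, seed = seed),
            class = "pm_archetype_scree")
}

#' @export
print.pm_archetype_scree <- function(x, ...) {
  cat("<pm_archetype_scree>\n")
  print(x$scree, row.names = FALSE)
  cat("selected k:", x$k_selected, "\n")
  invisible(x)
}

#' @export
plot.pm_archetype_scree <- function(x, ...) {
  graphics::plot(x$scree$k, x$scree$rss, type = "b", xlab = "Archetypes (k)",
                 ylab = "Best RSS", ...)
  graphics::abline(v = x$k_selected, lty = 2, col = "red3")
  invisible(x)
}
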