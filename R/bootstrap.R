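#' Bootstrap confidence intervals for curve parameters
#'
#' Nonparametric bootstrap: observation pairs (t, y) are resampled with
#' replacement, the curve is refitted by the chosen method, and the four
#' parameters are re-extracted; percentile intervals at
#' `(1 - level)/2` and `(1 + level)/2` are reported. Resamples on which the
#' refit fails (or yields no value for a parameter) are dropped and counted;
#' if more than half of the refits fail the intervals are flagged
#' unreliable. With a fixed seed the intervals are reproducible.
#'
#' For `method = "model"` the model family selected on the full data is held
#' fixed across resamples (re-running AIC selection inside the bootstrap
#' would mix model uncertainty into the intervals).
#'
#' No multiplicity adjustment is applied across parameters or curves, by
#' design: the per-curve CI workflow is meant to surface all potentially
#' interesting differences.
#'
#' @param curve A `pm_curve`.
#' @param method "spline" or "model".
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @param models Candidate model families for the full-data AIC selection
#'   (`method = "model"` only); the winner is then held fixed across
#'   resamples.
#' @param ... Passed to the fitting workhorse.
#' @return An object of class `pm_ci`: a list with `table` (data frame with
#'   columns `parameter`, `estimate`, `lower`, `upper`), `level`, `B`,
#'   `n_failed`, `seed`, `method` and `flags`. A point estimate lying outside
#'   its own percentile interval is flagged (`point_outside`), never
#'   reordered.
#' @examples
#' cv <- simulate_curve(shape_spec("logistic", noise_sd = 3), seed = 2)
#' bootstrap_cis(cv, B = 30, seed = 9)$table
#' @export
bootstrap_cis <- function(curve, method = c("spline", "model"), B = 100,
                          level = 0.95, seed = NULL,
                          models = growth_model_names(), ...) {
  stopifnot(inherits(curve, "pm_curve"), B >= 2, level > 0, level < 1)
  method <- match.arg(method)
  full <- if (method == "model") pm_fit(curve, "model", names = models, ...)
          else pm_fit(curve, method = method, ...)
  if (!full$params$fit_ok)
    stop("curve is not fittable by the ", method, " method", call. = FALSE)
  est <- coef(full)
  model_name <- if (method == "model") full$detail$best$model else NULL

  t <- curve$times; y <- curve$values; n <- length(t)
  refit_one <- function() {
    idx <- sort(sample.int(n, n, replace = TRUE))
    # resampling duplicates time points; a pm_curve needs strictly increasing
    # times, so tied draws are averaged with multiplicity as weight
    ts <- t[idx]; ys <- y[idx]
    w <- as.vector(table(ts))
    cvb <- tryCatch({
      agg <- rowsum(ys, ts) / w
      pm_curve(as.numeric(rownames(agg)), as.vector(agg))
    }, error = function(e) NULL)
    if (is.null(cvb)) return(rep(NA_real_, 4L))
    p <- tryCatch(switch(method,
      spline = fit_spline(cvb, eval_times = t, weights = w, ...)$params,
      model = fit_growth_model(cvb, model_name, auc_times = t,
                               weights = w, ...)$params),
      error = function(e) NULL)
    if (is.null(p) || !p$fit_ok) return(rep(NA_real_, 4L))
    coef(p)
  }
  draws <- .with_seed(seed, t(replicate(B, refit_one())))
  colnames(draws) <- names(est)
  failed <- sum(apply(draws, 1L, function(r) all(is.na(r))))
  flags <- character()
  if (failed > B / 2) flags <- c(flags, "unreliable_many_failures")

  probs <- c((1 - level) / 2, (1 + level) / 2)
  tab <- do.call(rbind, lapply(names(est), function(pn) {
    v <- draws[, pn]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      data.frame(parameter = pn, estimate = est[[pn]], lower = NA_real_,
                 upper = NA_real_, stringsAsFactors = FALSE)
    else {
      q <- stats::quantile(v, probs, names = FALSE, type = 7)
      data.frame(parameter = pn, estimate = est[[pn]], lower = q[1L],
                 upper = q[2L], stringsAsFactors = FALSE)
    }
  }))
  out_of <- with(tab, !is.na(lower) & !is.na(estimate) &
                   (estimate < lower | estimate > upper))
  if (any(out_of)) flags <- c(flags, "point_outside")
  structure(list(table = tab, level = level, B = B, n_failed = failed,
                 seed = seed, method = method, flags = flags),
            class = "pm_ci")
}

#' @export
print.pm_ci <- function(x, ...) {
  cat(sprintf("<pm_ci> %d%% percentile bootstrap (B=%d, method=%s, %d failed)\n",
              round(100 * x$level), x$B, x$method, x$n_failed))
  print(x$table, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
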