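#' Fit a respiration curve and extract its four parameters
#'
#' The central fitting function. Three estimation methods are available:
#' \describe{
#'   \item{"spline"}{cubic smoothing spline with tangent-based lag
#'     extraction (see [fit_spline()]); the recommended default -- it is
#'     total (never fails on finite data) and robust to non-sigmoid shapes.}
#'   \item{"model"}{nonlinear least-squares fits of the four standard growth
#'     models with AIC selection (see [select_best_model()]).}
#'   \item{"native"}{the instrument's own order-statistic algorithm (see
#'     [native_parameters()]); point estimates only.}
#' }
#'
#' @param curve A `pm_curve`.
#' @param method Estimation method.
#' @param ... Passed on to the method workhorse.
#' @return An object of class `pm_fit` with elements `curve`, `method`,
#'   `params` (`pm_params`) and `detail` (the method-specific fit object).
#'   Supports `coef()`, `fitted()`, `residuals()`, `predict()`, `plot()`,
#'   `print()` and `summary()`.
#' @examples
#' cv <- simulate_curve(shape_spec("logistic", A = 300, mu = 20, lambda = 10),
#'                      seed = 7)
#' f <- pm_fit(cv)
#' coef(f)
#' @export
pm_fit <- function(curve, method = c("spline", "model", "native"), ...) {
  stopifnot(inherits(curve, "pm_curve"))
  method <- match.arg(method)
  detail <- switch(method,
    spline = fit_spline(curve, ...),
    model = select_best_model(curve, ...),
    native = native_parameters(curve, ...))
  structure(list(curve = curve, method = method, params = detail$params,
                 detail = detail),
            class = "pm_fit")
}

#' @export
coef.pm_fit <- function(object, ...) coef(object$params)

#' @export
fitted.pm_fit <- function(object, ...) {
  switch(object$method,
    spline = object$detail$fitted,
    model = if (!is.null(object$detail$best)) object$detail$best$fitted,
    native = NULL)
}

#' @export
residuals.pm_fit <- function(object, ...) {
  f <- fitted(object)
  if (is.null(f)) return(NULL)
  object$curve$values - f
}

#' @export
predict.pm_fit <- function(object, newtimes = object$curve$times, ...) {
  switch(object$method,
    spline = stats::predict(object$detail$spline, newtimes, ...)$y,
    model = {
      b <- object$detail$best
      if (is.null(b)) stop("no converged model to predict from", call. = FALSE)
      growth_model_value(b$model, newtimes, b$coefficients)
    },
    native = stop("the native method does not define a fitted function",
                  call. = FALSE))
}

#' @export
print.pm_fit <- function(x, ...) {
  cat(sprintf("<pm_fit> well %s, method %s\n", x$curve$well, x$method))
  print(coef(x))
  if (length(x$params$flags))
    cat("flags:", paste(x$params$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pm_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              rss = if (!is.null(res)) sum(res^2) else NA_real_,
              n = length(object$curve$times))
  class(out) <- "summary.pm_fit"
  out
}

#' @export
print.summary.pm_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$method == "model" && !is.null(x$fit$detail$table)) {
    cat("model selection:\n")
    print(x$fit$detail$table, row.names = FALSE)
  }
  if (!is.na(x$rss))
    cat(sprintf("RSS %.4g on %d readings\n", x$rss, x$n))
  invisible(x)
}

#' @export
plot.pm_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$times, cv$values, pch = 1, cex = 0.5, xlab = "Time [h]",
                 ylab = "Value [OmniLog units]",
                 main = sprintf("%s (%s)", cv$well, x$method), ...)
  f <- fitted(x)
  if (!is.null(f)) graphics::lines(cv$times, f, col = "red3", lwd = 2)
  p <- x$params
  if (p$fit_ok && !is.na(p$lambda) && !is.na(p$mu)) {
    graphics::abline(a = -p$mu * p$lambda, b = p$mu, lty = 2, col = "grey40")
    graphics::abline(h = p$A, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Fit every curve of one or more plates
#'
#' @param plates A `pm_plate` or list of plates.
#' @param method Estimation method, as in [pm_fit()].
#' @param ... Passed to [pm_fit()].
#' @return A data frame in the [parameter_table()] layout, one row per curve,
#'   with a `flags` attribute (list of per-curve flag vectors).
#' @export
fit_plates <- function(plates, method = c("spline", "model", "native"), ...) {
  method <- match.arg(method)
  curves <- plate_curves(plates)
  fits <- lapply(curves, pm_fit, method = method, ...)
  tab <- parameter_table(fits)
  attr(tab, "flags") <- lapply(fits, function(f) f$params$flags)
  attr(tab, "fit_ok") <- vapply(fits, function(f) f$params$fit_ok, TRUE)
  tab
}

#' Table-style accounting of fit reliability
#'
#' Summarises a parameter table the way reliability is reported for PM
#' datasets: totals, curves without fittable models/splines, and counts of
#' implausible (`lambda < 0`, `A > cap`) and negative-reaction-range
#' (`A < threshold`) estimates.
#'
#' @param tab A parameter table from [fit_plates()] / [parameter_table()].
#' @param cap Instrument cap (units).
#' @param threshold Positivity threshold on `A` (units).
#' @return A one-row data frame of counts.
#' @export
fit_accounting <- function(tab, cap = 400, threshold = 100) {
  n <- nrow(tab)
  unfit <- sum(is.na(tab$A) & is.na(tab$mu) & is.na(tab$lambda) & is.na(tab$AUC))
  data.frame(
    n_total = n,
    n_unfittable = unfit,
    pct_unfittable = 100 * unfit / n,
    n_lambda_neg = sum(tab$lambda < 0, na.rm = TRUE),
    n_A_gt_cap = sum(tab$A > cap, na.rm = TRUE),
    n_A_le_threshold = sum(tab$A <= threshold, na.rm = TRUE))
}
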