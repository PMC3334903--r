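#' Growth model functional forms
#'
#' The four standard sigmoid growth models in the Zwietering
#' re-parameterisation, in which the biologically meaningful quantities --
#' maximum height `A` (OmniLog units), maximum slope `mu` (units/h) and lag
#' phase `lambda` (h) -- appear directly as model parameters:
#'
#' \describe{
#'   \item{logistic}{`y = A / (1 + exp(4 mu (lambda - t)/A + 2))`}
#'   \item{gompertz}{`y = A exp(-exp(mu e (lambda - t)/A + 1))`}
#'   \item{gompertz_exp}{modified Gompertz: the Gompertz term plus a late
#'     exponential rise `A exp(alpha (t - t_shift))`}
#'   \item{richards}{`y = A (1 + nu exp(1 + nu) exp((mu/A)(1 + nu)^(1 + 1/nu)
#'     (lambda - t)))^(-1/nu)`; `nu = 1` recovers the logistic}
#' }
#'
#' @param name Model name, one of `growth_model_names()`.
#' @param t Time(s) in hours.
#' @param pars Named numeric vector with `A`, `mu`, `lambda` and, as needed,
#'   `nu` (richards) or `alpha`, `t_shift` (gompertz_exp).
#' @return Model value(s) in OmniLog units.
#' @examples
#' growth_model_value("logistic", t = 10, c(A = 300, mu = 20, lambda = 10))
#' 300 / (1 + exp(2))
#' @export
growth_model_value <- function(name, t, pars) {
  name <- match.arg(name, growth_model_names())
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  need <- .model_par_names[[name]]
  if (!all(need %in% names(pars)) || any(!is.finite(pars[need])))
    stop("model '", name, "' needs finite parameters ",
         paste(need, collapse = ", "), call. = FALSE)
  A <- pars[["A"]]; mu <- pars[["mu"]]; lambda <- pars[["lambda"]]
  switch(name,
    logistic = A / (1 + exp(4 * mu * (lambda - t) / A + 2)),
    gompertz = A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1)),
    gompertz_exp = A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1)) +
      A * exp(pars[["alpha"]] * (t - pars[["t_shift"]])),
    richards = {
      nu <- pars[["nu"]]
      A * (1 + nu * exp(1 + nu) *
             exp((mu / A) * (1 + nu)^(1 + 1 / nu) * (lambda - t)))^(-1 / nu)
    })
}

#' @rdname growth_model_value
#' @export
growth_model_names <- function() c("logistic", "gompertz", "gompertz_exp", "richards")

.model_par_names <- list(
  logistic = c("A", "mu", "lambda"),
  gompertz = c("A", "mu", "lambda"),
  gompertz_exp = c("A", "mu", "lambda", "alpha", "t_shift"),
  richards = c("A", "mu", "lambda", "nu"))

.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

# Heuristic, reproducible starting values shared by all models. The initial
# slope is taken over a window of ~2.5% of the series so that measurement
# noise between adjacent readings does not dominate it.
.model_start <- function(curve, name) {
  t <- curve$times; y <- curve$values; n <- length(y)
  k <- max(1L, ceiling(n / 40))
  dq <- (y[(1L + k):n] - y[1:(n - k)]) / (t[(1L + k):n] - t[1:(n - k)])
  i <- which.max(dq)
  mu0 <- max(dq[i], 1e-3)
  A0 <- max(max(y), 1e-3)
  mid <- i + floor(k / 2)
  lam0 <- t[mid] - y[mid] / mu0
  st <- c(A = A0, mu = mu0, lambda = lam0)
  if (name == "richards") st <- c(st, nu = 1)
  if (name == "gompertz_exp") st <- c(st, alpha = 0.01, t_shift = max(t))
  st
}

.model_bounds <- function(name, trange) {
  lo <- c(A = 1e-6, mu = -Inf, lambda = -Inf)
  hi <- c(A = Inf, mu = Inf, lambda = Inf)
  if (name == "richards") { lo <- c(lo, nu = 1e-3); hi <- c(hi, nu = 50) }
  if (name == "gompertz_exp") {
    # the secondary term models a late rise inside the measured window; an
    # unconstrained t_shift escapes past the window and makes (alpha,
    # t_shift) unidentifiable
    lo <- c(lo, alpha = 0, t_shift = trange[1L])
    hi <- c(hi, alpha = 1, t_shift = trange[2L])
  }
  list(lower = lo, upper = hi)
}

#' Fit one growth model to a curve by nonlinear least squares
#'
#' Uses bounded Levenberg-Marquardt least squares with heuristic starting
#' values (A0 = max value; mu0 = max finite difference quotient; lambda0 from
#' the tangent through the steepest observed segment). Non-convergence is a
#' regular outcome, not an exception: the result carries `converged = FALSE`
#' and missing parameters. Biologically implausible estimates (negative lag,
#' maximum height above the instrument cap) are preserved unchanged and only
#' flagged.
#'
#' @param curve A `pm_curve`.
#' @param name Model name (see [growth_model_value()]).
#' @param cap Instrument cap used for the implausibility flag (OmniLog units).
#' @param maxit Iteration cap of the optimizer.
#' @param weights Optional observation weights (multiplicities of tied times
#'   in a bootstrap resample).
#' @param auc_times Time grid for the AUC integral of the fitted model
#'   (default: the curve's own times); bootstrap refits pass the original
#'   grid.
#' @return A list of class `pm_model_fit` with elements `model`, `coefficients`,
#'   `rss`, `n`, `p`, `aic`, `converged`, `flags`, `fitted` and the derived
#'   `params` (a `pm_params`; AUC by trapezoidal integration of the fitted
#'   curve over the observed time grid).
#' @export
fit_growth_model <- function(curve, name, cap = 400, maxit = 200,
                             weights = NULL, auc_times = NULL) {
  stopifnot(inherits(curve, "pm_curve"))
  name <- match.arg(name, growth_model_names())
  p <- length(.model_par_names[[name]])
  t <- curve$times; y <- curve$values; n <- length(t)
  fail <- function(flags) {
    structure(list(model = name, coefficients = NULL, rss = NA_real_, n = n,
                   p = p, aic = NA_real_, converged = FALSE, flags = flags,
                   fitted = NULL,
                   params = curve_params(method = "model", model_name = name,
                                         fit_ok = FALSE, flags = flags)),
              class = "pm_model_fit")
  }
  if (!curve$fittable || n < p + 2L) return(fail("too_few_points"))
  start <- .model_start(curve, name)
  b <- .model_bounds(name, range(t))
  form <- switch(name,
    logistic = y ~ A / (1 + exp(4 * mu * (lambda - t) / A + 2)),
    gompertz = y ~ A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1)),
    gompertz_exp = y ~ A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1)) +
      A * exp(alpha * (t - t_shift)),
    richards = y ~ A * (1 + nu * exp(1 + nu) *
      exp((mu / A) * (1 + nu)^(1 + 1 / nu) * (lambda - t)))^(-1 / nu))
  if (is.null(weights)) weights <- rep(1, n)
  try_fit <- function(st) tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      form, data = data.frame(y = y, t = t, w = weights),
      weights = w,
      start = as.list(st),
      lower = unname(b$lower[names(st)]),
      upper = unname(b$upper[names(st)]),
      control = minpack.lm::nls.lm.control(maxiter = maxit))),
    error = function(e) NULL)
  starts <- list(start)
  if (name == "gompertz_exp") {
    # the shift time of the secondary rise is weakly identified; a small
    # deterministic multi-start avoids boundary traps
    for (fr in c(0.5, 0.75)) {
      st <- start
      st[["t_shift"]] <- t[1L] + fr * (t[n] - t[1L])
      starts <- c(starts, list(st))
    }
  }
  fits <- Filter(Negate(is.null), lapply(starts, try_fit))
  if (!length(fits)) return(fail("no_convergence"))
  fit <- fits[[which.min(vapply(fits, function(f) sum(stats::resid(f)^2), 1))]]
  cf <- stats::coef(fit)[names(start)]
  if (any(!is.finite(cf))) return(fail("no_convergence"))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc))) return(fail("nonfinite_covariance"))
  fitted <- growth_model_value(name, t, cf)
  rss <- sum(weights * (y - fitted)^2)
  aic <- n * log(max(rss, 1e-300) / n) + 2 * (p + 1)
  flags <- character()
  if (cf[["lambda"]] < 0) flags <- c(flags, "lambda_negative")
  if (cf[["A"]] > cap) flags <- c(flags, "A_gt_cap")
  if (is.null(auc_times)) auc_times <- t
  params <- curve_params(
    lambda = cf[["lambda"]], mu = cf[["mu"]], A = cf[["A"]],
    AUC = .trapz(auc_times, growth_model_value(name, auc_times, cf)),
    method = "model", model_name = name,
    fit_ok = TRUE, flags = flags)
  structure(list(model = name, coefficients = cf, rss = rss, n = n, p = p,
                 aic = aic, converged = TRUE, flags = flags, fitted = fitted,
                 params = params),
            class = "pm_model_fit")
}

#' Fit all candidate growth models and select the best by AIC
#'
#' Each candidate is fitted by [fit_growth_model()]; for Gaussian least
#' squares the information criterion is `AIC = n ln(RSS/n) + 2 (p + 1)` with
#' `p` model parameters (+1 for the error variance). The converged model with
#' the lowest AIC wins; ties are broken by fewer parameters and then by the
#' fixed candidate order. If no candidate converges the curve is counted as
#' "without fittable models".
#'
#' @param curve A `pm_curve`.
#' @param names Candidate model names (default: all four).
#' @param cap Instrument cap for implausibility flags.
#' @return A list of class `pm_model_selection`: `best` (a `pm_model_fit`, or
#'   `NULL` if none converged), `table` (per-model data frame with RSS, AIC,
#'   convergence) and `params`.
#' @export
select_best_model <- function(curve, names = growth_model_names(), cap = 400) {
  names <- match.arg(names, growth_model_names(), several.ok = TRUE)
  fits <- lapply(names, function(nm) fit_growth_model(curve, nm, cap = cap))
  tab <- data.frame(
    model = names,
    p = vapply(fits, function(f) f$p, 1L),
    converged = vapply(fits, function(f) f$converged, TRUE),
    rss = vapply(fits, function(f) if (is.na(f$rss)) NA_real_ else f$rss, 1),
    aic = vapply(fits, function(f) if (is.na(f$aic)) NA_real_ else f$aic, 1),
    stringsAsFactors = FALSE)
  ok <- which(tab$converged)
  if (!length(ok)) {
    params <- curve_params(method = "model", fit_ok = FALSE,
                           flags = "unfittable")
    return(structure(list(best = NULL, table = tab, params = params),
                     class = "pm_model_selection"))
  }
  ord <- ok[order(tab$aic[ok], tab$p[ok], ok)]
  best <- fits[[ord[1L]]]
  structure(list(best = best, table = tab, params = best$params),
            class = "pm_model_selection")
}

#' @export
print.pm_model_selection <- function(x, ...) {
  cat("<pm_model_selection>\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$best)) cat("best:", x$best$model, "\n")
  else cat("no model converged\n")
  invisible(x)
}
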