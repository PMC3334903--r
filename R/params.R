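#' Curve-parameter container
#'
#' Holds the four canonical curve parameters with method provenance: lag
#' phase `lambda` (h), maximum slope `mu` (units/h), maximum height `A`
#' (units) and `AUC` (unit x hours for the model and spline conventions; a
#' plain unit-sum over readings for the native convention). If `fit_ok` is
#' `FALSE` all four parameters are `NA`. Implausible values (negative lambda,
#' A above the instrument cap) are never altered, only flagged.
#'
#' @param lambda,mu,A,AUC Parameter values (may be `NA`).
#' @param method One of "native", "model", "spline".
#' @param model_name Selected model for the model method.
#' @param fit_ok Logical; `FALSE` marks an unfittable curve.
#' @param flags Character vector of quality flags.
#' @return An object of class `pm_params`.
#' @export
curve_params <- function(lambda = NA_real_, mu = NA_real_, A = NA_real_,
                         AUC = NA_real_,
                         method = c("native", "model", "spline"),
                         model_name = NA_character_, fit_ok = TRUE,
                         flags = character()) {
  method <- match.arg(method)
  if (!fit_ok) lambda <- mu <- A <- AUC <- NA_real_
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu),
                 A = as.numeric(A), AUC = as.numeric(AUC),
                 method = method, model_name = model_name,
                 fit_ok = isTRUE(fit_ok), flags = flags),
            class = "pm_params")
}

#' @export
coef.pm_params <- function(object, ...) {
  c(lambda = object$lambda, mu = object$mu, A = object$A, AUC = object$AUC)
}

#' @export
print.pm_params <- function(x, ...) {
  cat(sprintf("<pm_params> method=%s%s fit_ok=%s\n", x$method,
              if (!is.na(x$model_name)) paste0(" (", x$model_name, ")") else "",
              x$fit_ok))
  print(coef(x))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a parameter table from fits
#'
#' Collects per-curve parameter estimates (and bootstrap CI limits, when
#' present) into the fixed 18-column layout used by
#' [write_parameter_table()].
#'
#' @param fits A list of `pm_fit` objects (see [pm_fit()]), or a list of
#'   `pm_params`.
#' @param cis Optional list of `pm_ci` objects parallel to `fits`.
#' @param dataset_id,plate_id Identifier defaults used when a fit's curve
#'   carries none.
#' @return A data frame with columns `dataset_id, plate_id, well, substrate,
#'   method, model_name, lambda, lambda_lo, lambda_hi, mu, mu_lo, mu_hi, A,
#'   A_lo, A_hi, AUC, AUC_lo, AUC_hi`.
#' @export
parameter_table <- function(fits, cis = NULL, dataset_id = "ds1",
                            plate_id = "plate1") {
  if (inherits(fits, "pm_fit") || inherits(fits, "pm_params"))
    fits <- list(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    pp <- if (inherits(f, "pm_params")) f else f$params
    cv <- if (inherits(f, "pm_fit")) f$curve else NULL
    row <- data.frame(
      dataset_id = if (!is.null(cv) && !is.null(cv$dataset_id)) cv$dataset_id else dataset_id,
      plate_id = if (!is.null(cv) && !is.null(cv$plate_id)) cv$plate_id else plate_id,
      well = if (!is.null(cv)) cv$well else NA_character_,
      substrate = if (!is.null(cv)) cv$substrate else NA_character_,
      method = pp$method, model_name = pp$model_name,
      lambda = pp$lambda, lambda_lo = NA_real_, lambda_hi = NA_real_,
      mu = pp$mu, mu_lo = NA_real_, mu_hi = NA_real_,
      A = pp$A, A_lo = NA_real_, A_hi = NA_real_,
      AUC = pp$AUC, AUC_lo = NA_real_, AUC_hi = NA_real_,
      stringsAsFactors = FALSE)
    ci <- if (!is.null(cis)) cis[[i]] else NULL
    if (!is.null(ci)) {
      tb <- ci$table
      for (pn in tb$parameter) {
        row[[paste0(sub("^lambda$", "lambda", pn), "_lo")]] <-
          tb$lower[tb$parameter == pn]
        row[[paste0(pn, "_hi")]] <- tb$upper[tb$parameter == pn]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(cis)) {
    lev <- unique(unlist(lapply(cis, function(ci) ci$level)))
    if (length(lev) > 1L) stop("mixed CI levels", call. = FALSE)
    attr(out, "ci_level") <- lev
  }
  out
}
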