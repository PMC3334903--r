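#' Re-implementation of the instrument's native parametric algorithm
#'
#' The OmniLog PM software derives curve parameters from a handful of order
#' statistics and threshold crossings of the raw readings, without fitting any
#' function:
#'
#' \itemize{
#'   \item `MaxHeight`: the 10th-percentile-highest value among all readings.
#'     By default this is read as the nearest-rank 90th percentile of all
#'     readings (`max_rule = "percentile"`); the alternative literal reading,
#'     the 10th-highest single reading, is available as
#'     `max_rule = "tenth_highest"`.
#'   \item `MinHeight`: the 12th-smallest value among the first 48 readings
#'     (all readings, flagged, when fewer than 48 are available).
#'   \item `MidHeight = (MinHeight + MaxHeight) / 2`; `MidTime` is the first
#'     time a reading strictly exceeds MidHeight. No interpolation is used
#'     anywhere: crossings are literal first samples.
#'   \item `x% Time`: the first time a reading exceeds
#'     `MinHeight + x (MaxHeight - MinHeight)`.
#'   \item `Slope`: total rise over the readings from the 15%-time up to one
#'     sample before MidTime, plus the total rise from one sample after
#'     MidTime up to the 85%-time, divided by (85%-time - 15%-time). The
#'     reading at MidTime itself is excluded.
#'   \item `lambda = MidTime - (MidHeight - MinHeight) / Slope`; `mu = Slope`;
#'     `A = MaxHeight`; `AUC` is the plain sum of all readings (step-function
#'     convention, so its unit is OmniLog-units x readings, not x hours).
#' }
#'
#' The native method yields point estimates only (no confidence intervals).
#' On a curve that never exceeds MidHeight (e.g. a constant curve) MidTime is
#' undefined; lambda and mu are then `NA` and flagged while `A` and `AUC` are
#' still returned.
#'
#' @param curve A `pm_curve`.
#' @param max_rule How to read "10th percentile highest value"; see above.
#' @return A list of class `pm_native_fit` with the `params` (`pm_params`,
#'   method "native") and the `intermediates` (MaxHeight, MinHeight,
#'   MidHeight, MidTime, PctTime15, PctTime85, Slope).
#' @examples
#' cv <- pm_curve(0:9, c(0, 0, 0, 10, 50, 120, 200, 250, 260, 260))
#' native_parameters(cv)$intermediates
#' @export
native_parameters <- function(curve, max_rule = c("percentile", "tenth_highest")) {
  stopifnot(inherits(curve, "pm_curve"))
  max_rule <- match.arg(max_rule)
  t <- curve$times; y <- curve$values; n <- length(y)
  flags <- character()
  if (n < 4L) {
    return(structure(list(
      params = curve_params(method = "native", fit_ok = FALSE,
                            flags = "too_few_points"),
      intermediates = NULL), class = "pm_native_fit"))
  }
  maxh <- switch(max_rule,
    percentile = sort(y)[max(1L, ceiling(0.9 * n))],
    tenth_highest = if (n >= 10L) sort(y, decreasing = TRUE)[10L] else {
      flags <- c(flags, "short_series"); max(y)
    })
  first48 <- y[seq_len(min(48L, n))]
  if (n < 48L) flags <- c(flags, "fewer_than_48_reads")
  # 12th smallest of the first 48 reads; on series shorter than 12 reads the
  # rank is undefined and the plain minimum serves as the baseline
  minh <- if (length(first48) >= 12L) sort(first48)[12L] else min(first48)
  midh <- (minh + maxh) / 2

  first_exceed <- function(th) {
    i <- which(y > th)
    if (length(i)) i[1L] else NA_integer_
  }
  i_mid <- first_exceed(midh)
  i_15 <- first_exceed(minh + 0.15 * (maxh - minh))
  i_85 <- first_exceed(minh + 0.85 * (maxh - minh))

  auc <- sum(y)
  slope <- NA_real_
  lambda <- NA_real_
  inter <- list(MaxHeight = maxh, MinHeight = minh, MidHeight = midh,
                MidTime = if (is.na(i_mid)) NA_real_ else t[i_mid],
                PctTime15 = if (is.na(i_15)) NA_real_ else t[i_15],
                PctTime85 = if (is.na(i_85)) NA_real_ else t[i_85],
                Slope = NA_real_)

  if (is.na(i_mid) || is.na(i_15) || is.na(i_85)) {
    flags <- c(flags, "midtime_undefined")
  } else if (t[i_85] == t[i_15]) {
    flags <- c(flags, "degenerate_slope_window")
  } else {
    # total rise over each window; consecutive rises telescope to the
    # endpoint difference, and the MidTime reading itself is excluded
    rise1 <- if (i_mid - 1L >= i_15) y[i_mid - 1L] - y[i_15] else 0
    rise2 <- if (i_85 >= i_mid + 1L) y[i_85] - y[i_mid + 1L] else 0
    slope <- (rise1 + rise2) / (t[i_85] - t[i_15])
    inter$Slope <- slope
    if (slope == 0) {
      flags <- c(flags, "zero_slope")
      slope <- NA_real_
    } else {
      lambda <- t[i_mid] - (midh - minh) / slope
    }
  }
  params <- curve_params(lambda = lambda, mu = slope, A = maxh, AUC = auc,
                         method = "native", fit_ok = TRUE, flags = flags)
  structure(list(params = params, intermediates = inter),
            class = "pm_native_fit")
}

#' @export
print.pm_native_fit <- function(x, ...) {
  cat("<pm_native_fit>\n")
  print(x$params)
  invisible(x)
}

#' Native step-function area under the curve
#'
#' The native convention sums all readings, treating the curve as a step
#' function; the result is in OmniLog-units x readings. For steep curves this
#' (rescaled by the sampling step) slightly exceeds the trapezoidal area on
#' the same points.
#'
#' @param curve A `pm_curve`.
#' @return The plain sum of all readings.
#' @export
native_auc <- function(curve) {
  stopifnot(inherits(curve, "pm_curve"))
  sum(curve$values)
}
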