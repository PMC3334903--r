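#' Flag raw-data artifacts in a kinetic curve
#'
#' Respiration kinetics are expected to increase monotonically; two kinds of
#' departures show up in raw PM data and are worth flagging before fitting:
#' runs of decreasing readings (loss of colour intensity) and short-term
#' intermediate peaks, i.e. a single reading that juts above both of its
#' neighbours.
#'
#' A drop report covers a maximal run of consecutive readings over which the
#' value decreases by more than `drop_tol` in total. A spike report covers a
#' single reading exceeding both neighbours by more than `drop_tol`.
#'
#' @param curve A `pm_curve`.
#' @param drop_tol Tolerance in OmniLog units; must be > 0. Declines and
#'   excursions not exceeding it are treated as noise.
#' @return A data frame with one row per artifact and columns `well`, `kind`
#'   ("non-monotone-drop" or "transient-spike"), `from`, `to` (reading
#'   indices) and `magnitude` (units). Zero rows for clean curves.
#' @examples
#' y <- c(0, 5, 10, 80, 12, 14, 16)
#' flag_curve_artifacts(pm_curve(0:6, y), drop_tol = 10)
#' @export
flag_curve_artifacts <- function(curve, drop_tol = 10) {
  stopifnot(inherits(curve, "pm_curve"), drop_tol > 0)
  y <- curve$values
  n <- length(y)
  rep0 <- data.frame(well = character(), kind = character(),
                     from = integer(), to = integer(),
                     magnitude = numeric(), stringsAsFactors = FALSE)
  if (n < 3L) return(rep0)

  spikes <- which(vapply(2:(n - 1L), function(i)
    (y[i] - y[i - 1L]) > drop_tol && (y[i] - y[i + 1L]) > drop_tol, TRUE)) + 1L

  out <- rep0
  for (i in spikes)
    out <- rbind(out, data.frame(
      well = curve$well, kind = "transient-spike", from = i, to = i,
      magnitude = y[i] - max(y[i - 1L], y[i + 1L]),
      stringsAsFactors = FALSE))

  # maximal runs of non-increasing values, reported when the total decline
  # exceeds the tolerance; spike shoulders are part of such runs too, which
  # is intended (the decline is real either way)
  i <- 1L
  while (i < n) {
    if (y[i + 1L] < y[i]) {
      j <- i
      while (j < n && y[j + 1L] <= y[j]) j <- j + 1L
      if (y[i] - y[j] > drop_tol)
        out <- rbind(out, data.frame(
          well = curve$well, kind = "non-monotone-drop", from = i, to = j,
          magnitude = y[i] - y[j], stringsAsFactors = FALSE))
      i <- j
    } else i <- i + 1L
  }
  rownames(out) <- NULL
  out
}
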