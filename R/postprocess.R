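#' Positive/negative reaction calls from maximum height
#'
#' A (partially arbitrary) threshold of 100 OmniLog units on the maximum
#' height A separates positive from negative reactions: estimates strictly
#' above the threshold are called positive, all others negative. Missing A
#' yields a no-call.
#'
#' @param A Numeric vector of maximum-height estimates (units).
#' @param threshold Positivity threshold (units).
#' @return Character vector: "positive", "negative" or `NA` (no-call).
#' @examples
#' call_reaction(c(150, 100, 0, NA))
#' @export
call_reaction <- function(A, threshold = 100) {
  out <- ifelse(A > threshold, "positive", "negative")
  out[is.na(A)] <- NA_character_
  out
}

#' Symmetrise a lag-phase column by truncation
#'
#' Spline lag estimates for intrinsically negative reactions can be extreme
#' negative outliers. For post-processing (e.g. before archetype analysis)
#' the distribution is made symmetrical: with `M = max(values)`, every value
#' below `-M` is set to `-M`. Idempotent; other values are untouched.
#'
#' @param values Numeric vector of lag estimates (h); `NA`s pass through.
#' @return The truncated vector.
#' @examples
#' truncate_lambda(c(-500, -2, 5, 10))  # -> -10 -2 5 10
#' @export
truncate_lambda <- function(values) {
  if (all(is.na(values))) stop("all values missing", call. = FALSE)
  M <- max(values, na.rm = TRUE)
  values[!is.na(values) & values < -M] <- -M
  values
}

#' Rank correlations between curve parameters
#'
#' All-against-all Spearman or Kendall correlations across parameter columns
#' (typically the 4 + 4 columns of two fitting methods on the same curves).
#' Rank correlations are used because the parameter distributions are not
#' necessarily normal nor the relationships linear. Constant columns have no
#' defined rank correlation and yield `NA`.
#'
#' @param table Numeric matrix or data frame of parameter columns.
#' @param method "spearman" or "kendall".
#' @return Correlation matrix.
#' @export
parameter_correlations <- function(table, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  if (sum(stats::complete.cases(X)) < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  suppressWarnings(stats::cor(X, method = method,
                              use = "pairwise.complete.obs"))
}
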