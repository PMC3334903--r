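#' Read and write plate kinetics in the OmniLog CSV dialect
#'
#' The dialect mirrors typical instrument exports: optional leading metadata
#' lines starting with `#` (recognised keys: `plate_id`, `dataset_id`), then a
#' header whose first column is the time in decimal hours (named "Hour" or
#' "Time") followed by one column per well ("A01" ... "H12"; unpadded labels
#' are accepted and canonicalised). Times given in another unit can be
#' rescaled via `time_scale` (e.g. 1/60 for minutes).
#'
#' @param source Path to a CSV file (or a connection).
#' @param time_scale Multiplier applied to the time column to obtain hours.
#' @return A list of `pm_plate` objects (one per file in this dialect). Wells
#'   absent from the header are recorded in the plate's `missing_wells`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' pl <- simulate_experiment(pm_design(strains = "K12"), seed = 1)[[1]]
#' write_omnilog_csv(pl, tf)
#' pl2 <- read_omnilog_csv(tf)[[1]]
#' all.equal(pl2$times, pl$times)
#' @export
read_omnilog_csv <- function(source, time_scale = 1) {
  lines <- readLines(source)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows found", call. = FALSE)
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("header must contain a time column and at least one well column",
         call. = FALSE)
  tnm <- names(tab)[1L]
  if (!grepl("^(hour|time)", tolower(tnm)))
    stop("malformed header: first column '", tnm,
         "' is not a time column (expected 'Hour' or 'Time')", call. = FALSE)
  wells_raw <- names(tab)[-1L]
  ok <- grepl("^[A-Ha-h]0?[1-9][0-2]?$", wells_raw)
  if (any(!ok))
    stop("malformed header: not a well label: ",
         paste(wells_raw[!ok], collapse = ", "), call. = FALSE)
  labs <- parse_well(wells_raw)$label
  times <- as.numeric(tab[[1L]]) * time_scale
  if (anyNA(times) || any(diff(times) <= 0))
    stop("time column must be numeric and strictly increasing", call. = FALSE)

  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*[:=]"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, "\\s*[:=]"), "", hit[1L]))
    else default
  }
  plate_id <- get_meta("plate_id", basename(as.character(source)))
  dataset_id <- get_meta("dataset_id", "ds1")

  curves <- lapply(seq_along(labs), function(j)
    pm_curve(times, as.numeric(tab[[j + 1L]]), well = labs[j]))
  list(pm_plate(curves, plate_id = plate_id, dataset_id = dataset_id))
}

#' @rdname read_omnilog_csv
#' @param plate A `pm_plate`.
#' @param sink Path of the CSV file to write.
#' @param digits Significant digits used for values.
#' @export
write_omnilog_csv <- function(plate, sink, digits = 10) {
  stopifnot(inherits(plate, "pm_plate"))
  hdr <- c(sprintf("# plate_id: %s", plate$plate_id),
           sprintf("# dataset_id: %s", plate$dataset_id))
  labs <- names(plate$curves)
  mat <- vapply(plate$curves, function(cv) cv$values,
                numeric(length(plate$times)))
  con <- file(sink, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("Hour", labs), collapse = ","), con)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  body <- apply(cbind(plate$times, mat), 1L,
                function(r) paste(fmt(r), collapse = ","))
  writeLines(body, con)
  invisible(sink)
}

.partab_cols <- c("dataset_id", "plate_id", "well", "substrate", "method",
                  "model_name",
                  "lambda", "lambda_lo", "lambda_hi",
                  "mu", "mu_lo", "mu_hi",
                  "A", "A_lo", "A_hi",
                  "AUC", "AUC_lo", "AUC_hi")

#' Write and read curve-parameter tables
#'
#' One row per (curve, method) with fixed columns: dataset_id, plate_id, well,
#' substrate, method, model_name, then estimate/lower/upper triples for the
#' four parameters (lambda, mu, A, AUC). CI cells are left empty when no
#' confidence intervals were computed. Rows are ordered by (dataset, plate,
#' well, method) so repeated writes are byte-identical.
#'
#' @param params A data frame in the parameter-table layout (as returned by
#'   `parameter_table()`), possibly with CI columns filled.
#' @param sink Path of the CSV file to write.
#' @param level Optional CI level; all rows of a table must share one level.
#' @return `write_parameter_table()` invisibly returns the path;
#'   `read_parameter_table()` returns the table as a data frame.
#' @export
write_parameter_table <- function(params, sink, level = NULL) {
  params <- as.data.frame(params, stringsAsFactors = FALSE)
  miss <- setdiff(.partab_cols, names(params))
  for (cn in miss) params[[cn]] <- NA_real_
  params <- params[, .partab_cols]
  lv <- attr(params, "ci_level")
  if (!is.null(level) && !is.null(lv) && length(unique(c(level, lv))) > 1L)
    stop("mixed CI levels in one parameter table", call. = FALSE)
  ord <- order(params$dataset_id, params$plate_id, params$well, params$method)
  params <- params[ord, , drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, digits = 10, format = "g"))
    else ifelse(is.na(x), "", as.character(x))
  }
  out <- if (nrow(params))
    matrix(unlist(lapply(params, fmt)), nrow = nrow(params))
  con <- file(sink, "w")
  on.exit(close(con))
  writeLines(paste(.partab_cols, collapse = ","), con)
  if (nrow(params))
    writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(sink)
}

#' @rdname write_parameter_table
#' @param source Path of a parameter-table CSV.
#' @export
read_parameter_table <- function(source) {
  tab <- utils::read.csv(source, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = c(rep("character", 6L), rep("numeric", 12L)))
  if (!identical(names(tab), .partab_cols))
    stop("not a pmkin parameter table: unexpected columns", call. = FALSE)
  tab
}

#' Subtract the negative-control well from all other wells
#'
#' The substrate-free control well (A01 on GEN III plates) is sometimes
#' subtracted from all other wells before analysis. This transformation is
#' deliberately not applied by default anywhere in the package -- control
#' curves can show reproducible strain-specific behaviour of their own, so raw
#' values are the recommended basis for fitting -- but it is provided for
#' users who need it.
#'
#' @param plate A `pm_plate`.
#' @param control Label of the control well.
#' @return A new `pm_plate` with the control curve subtracted from every other
#'   well (the control well itself is set to zero).
#' @export
subtract_control <- function(plate, control = "A01") {
  stopifnot(inherits(plate, "pm_plate"))
  control <- parse_well(control)$label
  if (is.null(plate$curves[[control]]))
    stop("control well ", control, " not present on plate", call. = FALSE)
  ref <- plate$curves[[control]]$values
  curves <- lapply(plate$curves, function(cv) {
    cv$values <- cv$values - ref
    cv
  })
  pm_plate(curves, plate_id = plate$plate_id, dataset_id = plate$dataset_id)
}
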