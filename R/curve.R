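#' Kinetic curve and plate containers
#'
#' A `pm_curve` holds one well's respiration time series: measurement times in
#' hours, readings in OmniLog units, the well coordinate and experimental
#' metadata. A `pm_plate` bundles the 96 curves of one plate, which must share
#' a common time grid.
#'
#' @param times Numeric vector of measurement times in hours, strictly
#'   increasing, all >= 0.
#' @param values Numeric vector of OmniLog readings, same length as `times`.
#' @param well Well label (e.g. "A01").
#' @param strain,biol_rep,tech_rep,substrate Optional metadata strings.
#' @param cultivation Optional cultivation duration of the inoculum in hours.
#' @return An object of class `pm_curve`.
#' @examples
#' cv <- pm_curve(0:10, c(0, 1, 3, 8, 20, 45, 80, 110, 125, 130, 131))
#' print(cv)
#' @export
pm_curve <- function(times, values, well = "A01", strain = NA_character_,
                     biol_rep = NA_character_, tech_rep = NA_character_,
                     cultivation = NA_real_, substrate = NA_character_) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  keep <- !(is.na(times) | is.na(values))
  dropped <- sum(!keep)
  times <- times[keep]
  values <- values[keep]
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(times) && times[1L] < 0)
    stop("times must be >= 0", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  structure(
    list(times = times, values = values,
         well = parse_well(well)$label,
         strain = strain, biol_rep = biol_rep, tech_rep = tech_rep,
         cultivation = cultivation, substrate = substrate,
         n_dropped = dropped,
         fittable = length(times) >= 4L),
    class = "pm_curve")
}

#' @export
print.pm_curve <- function(x, ...) {
  cat(sprintf("<pm_curve> well %s: %d readings over %.2f-%.2f h, range %.1f-%.1f units\n",
              x$well, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              if (length(x$values)) min(x$values) else NA,
              if (length(x$values)) max(x$values) else NA))
  if (!is.na(x$strain)) cat("  strain:", x$strain, "\n")
  invisible(x)
}

#' @export
plot.pm_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "Time [h]",
                 ylab = "Value [OmniLog units]", main = x$well, ...)
  invisible(x)
}

#' @rdname pm_curve
#' @param curves List of `pm_curve` objects, at most one per well.
#' @param plate_id,dataset_id Identifier strings.
#' @param require_full If `TRUE`, all 96 wells must be present.
#' @export
pm_plate <- function(curves, plate_id = "plate1", dataset_id = "ds1",
                     require_full = FALSE) {
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "pm_curve")))
    stop("curves must be a non-empty list of pm_curve objects", call. = FALSE)
  labs <- vapply(curves, function(cv) cv$well, "")
  if (anyDuplicated(labs))
    stop("duplicate wells in plate: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  names(curves) <- labs
  ref <- curves[[1L]]$times
  same <- vapply(curves, function(cv)
    length(cv$times) == length(ref) && all(cv$times == ref), TRUE)
  if (!all(same))
    stop("all curves on a plate must share one time grid", call. = FALSE)
  missing <- setdiff(well_labels(), labs)
  if (require_full && length(missing))
    stop("plate is missing wells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  curves <- curves[intersect(well_labels(), labs)]  # canonical plate order
  curves <- lapply(curves, function(cv) {
    cv$plate_id <- plate_id
    cv$dataset_id <- dataset_id
    cv
  })
  structure(list(curves = curves, times = ref, plate_id = plate_id,
                 dataset_id = dataset_id, missing_wells = missing),
            class = "pm_plate")
}

#' @export
print.pm_plate <- function(x, ...) {
  cat(sprintf("<pm_plate> %s (dataset %s): %d wells, %d time points (%.2f-%.2f h)\n",
              x$plate_id, x$dataset_id, length(x$curves), length(x$times),
              min(x$times), max(x$times)))
  if (length(x$missing_wells))
    cat("  missing wells:", length(x$missing_wells), "\n")
  invisible(x)
}

#' @export
length.pm_plate <- function(x) length(x$curves)

#' @export
`[[.pm_plate` <- function(x, i) {
  if (is.character(i)) i <- parse_well(i)$label
  x$curves[[i]]
}

#' Flatten plates into a list of curves
#'
#' @param plates A `pm_plate` or list of `pm_plate` objects.
#' @return A flat list of `pm_curve` objects.
#' @export
plate_curves <- function(plates) {
  if (inherits(plates, "pm_plate")) plates <- list(plates)
  unlist(lapply(plates, function(p) p$curves), recursive = FALSE)
}
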