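#' Trellis grid of plate kinetics
#'
#' Draws the curves of one or more plates as small multiples arranged in the
#' original 8 x 12 plate layout (or any subset of wells), with one panel per
#' well and one curve per group superimposed in each panel -- the most
#' informative raw-data display for spotting deviating replicates, artifacts
#' and non-sigmoid shapes.
#'
#' All plot functions return their drawing data ("layers") so that tests and
#' downstream code can inspect what would be drawn without rendering pixels;
#' rendering happens only when `out` is given (vector formats by default).
#'
#' @param plates A `pm_plate` or list of plates.
#' @param group_by How to colour curves: a function `(curve) -> value` or the
#'   name of a curve metadata field ("strain", "tech_rep", ...).
#' @param wells Optional subset of well labels; default all wells present.
#' @param colors Optional named colour map, one entry per group; must be
#'   injective over groups.
#' @param out Optional output path; the format is taken from the extension
#'   (pdf, svg or png).
#' @return Invisibly, an object of class `pm_plot` with elements `data` (long
#'   data frame: time, value, well, group), `panels` (well labels, one per
#'   panel), `layout`, `colors` and `trellis` (the lattice object).
#' @export
plot_plate_grid <- function(plates, group_by = "strain", wells = NULL,
                            colors = NULL, out = NULL) {
  curves <- plate_curves(plates)
  if (!length(curves)) stop("no plates given", call. = FALSE)
  getg <- if (is.function(group_by)) group_by
          else function(cv) as.character(cv[[group_by]])
  if (!is.null(wells)) {
    wells <- parse_well(wells)$label
    curves <- Filter(function(cv) cv$well %in% wells, curves)
  }
  dat <- do.call(rbind, lapply(curves, function(cv) {
    g <- getg(cv)
    data.frame(time = cv$times, value = cv$values, well = cv$well,
               group = if (is.null(g) || is.na(g)) "all" else g,
               stringsAsFactors = FALSE)
  }))
  panels <- sort(unique(dat$well))
  groups <- sort(unique(dat$group))
  if (is.null(colors)) {
    colors <- stats::setNames(
      grDevices::hcl.colors(max(length(groups), 2L), "Dark 3")[seq_along(groups)],
      groups)
  } else {
    if (!all(groups %in% names(colors)))
      stop("color map lacks group(s): ",
           paste(setdiff(groups, names(colors)), collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(colors[groups]))
      stop("color map must be injective over groups", call. = FALSE)
  }
  ncol_ <- if (length(panels) == 96L) 12L
           else as.integer(ceiling(sqrt(length(panels))))
  nrow_ <- as.integer(ceiling(length(panels) / ncol_))
  dat$well <- factor(dat$well, levels = panels)
  tr <- lattice::xyplot(value ~ time | well, data = dat,
                        groups = dat$group, type = "l",
                        col = unname(colors[groups]),
                        layout = c(ncol_, nrow_),
                        xlab = "Time [h]", ylab = "Value [OmniLog units]",
                        as.table = TRUE)
  obj <- structure(list(kind = "plate_grid", data = dat, panels = panels,
                        layout = c(ncol_, nrow_), colors = colors[groups],
                        trellis = tr),
                   class = "pm_plot")
  if (!is.null(out)) .render_plot(obj, out)
  invisible(obj)
}

#' Level-map (heat strip) display of plate kinetics
#'
#' Each curve becomes one thin horizontal strip whose colour intensity codes
#' the reading; strips are stacked (one per well, plates concatenated) over a
#' common time axis. Many curves fit in little space, and departures from
#' monotone colour build-up stand out. The strip order is freely
#' user-definable.
#'
#' @param plates A `pm_plate` or list of plates sharing one time grid.
#' @param order Optional permutation (indices into the stacked curve list) or
#'   character vector of `plate/well` ids defining the strip order from the
#'   bottom up.
#' @param out Optional output path (pdf/svg/png).
#' @return Invisibly, a `pm_plot` with `data` (matrix: one row per strip),
#'   `strips` (ids in display order) and `trellis`.
#' @export
plot_levelmap <- function(plates, order = NULL, out = NULL) {
  curves <- plate_curves(plates)
  if (!length(curves)) stop("no plates given", call. = FALSE)
  times <- curves[[1L]]$times
  same <- vapply(curves, function(cv)
    length(cv$times) == length(times) && all(cv$times == times), TRUE)
  if (!all(same)) stop("level map needs a common time grid", call. = FALSE)
  ids <- vapply(curves, function(cv)
    paste(if (is.null(cv$plate_id)) "plate" else cv$plate_id, cv$well,
          sep = "/"), "")
  if (!is.null(order)) {
    idx <- if (is.character(order)) match(order, ids) else as.integer(order)
    if (anyNA(idx) || length(idx) != length(curves) || anyDuplicated(idx))
      stop("order must be a permutation of the strips", call. = FALSE)
    curves <- curves[idx]; ids <- ids[idx]
  }
  mat <- t(vapply(curves, function(cv) cv$values, numeric(length(times))))
  rownames(mat) <- ids
  tr <- lattice::levelplot(t(mat), aspect = "fill",
                           col.regions = grDevices::hcl.colors(100, "YlOrRd",
                                                               rev = TRUE),
                           xlab = "Reading", ylab = NULL)
  obj <- structure(list(kind = "levelmap", data = mat, strips = ids,
                        times = times, trellis = tr),
                   class = "pm_plot")
  if (!is.null(out)) .render_plot(obj, out)
  invisible(obj)
}

#' Dot-and-whisker panels of parameter CIs
#'
#' One panel per parameter (lambda, mu, A, AUC); each curve or group
#' contributes a point estimate with its CI whisker. A reference id can be
#' highlighted: vertical lines are drawn at its lower and upper limits so
#' non-overlap with other whiskers (and hence a statistically detectable
#' difference, with the gap as the minimum expectable difference) is
#' immediate. For difference-of-means tables (`differences = TRUE`, e.g.
#' from [simultaneous_mean_differences()]) the reference lines sit at zero:
#' an interval missing zero flags a detectable group difference.
#'
#' @param ci_table Data frame with columns `id`, `parameter`, `estimate`,
#'   `lower`, `upper` (stack `pm_ci` tables or a [group_mean_cis()] /
#'   `pm_comparison` result with an added `id`).
#' @param reference Optional id whose limits are highlighted.
#' @param level The shared CI level (display only); mixing levels is an
#'   error upstream, so one value is required here.
#' @param differences Treat the table as differences of means.
#' @param out Optional output path (pdf/svg/png).
#' @return Invisibly, a `pm_plot` with `data` (the table), `reference_lines`
#'   (per-parameter data frame of highlighted limits) and `trellis`.
#' @export
plot_parameter_cis <- function(ci_table, reference = NULL, level = 0.95,
                               differences = FALSE, out = NULL) {
  need <- c("id", "parameter", "estimate", "lower", "upper")
  if (!all(need %in% names(ci_table)))
    stop("ci_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("level" %in% names(ci_table)) {
    if (length(unique(ci_table$level)) > 1L)
      stop("mixed CI levels", call. = FALSE)
    level <- ci_table$level[1L]
  }
  pars <- unique(ci_table$parameter)
  refs <- if (differences) {
    data.frame(parameter = pars, lower = 0, upper = 0,
               stringsAsFactors = FALSE)
  } else if (!is.null(reference)) {
    sub <- ci_table[ci_table$id == reference, c("parameter", "lower", "upper")]
    if (!nrow(sub)) stop("reference id not in table", call. = FALSE)
    sub
  } else NULL
  ci_table$id <- factor(ci_table$id, levels = unique(ci_table$id))
  tr <- lattice::xyplot(
    id ~ estimate | parameter, data = ci_table,
    lo = ci_table$lower, hi = ci_table$upper, refs = refs,
    scales = list(x = list(relation = "free")),
    xlab = sprintf("Estimate with %d%% CI", round(100 * level)),
    panel = function(x, y, lo, hi, refs, subscripts, ...) {
      lattice::panel.segments(lo[subscripts], y, hi[subscripts], y)
      lattice::panel.points(x, y, pch = 16)
      if (!is.null(refs)) {
        pn <- as.character(ci_table$parameter[subscripts][1L])
        r <- refs[refs$parameter == pn, ]
        if (nrow(r)) {
          lattice::panel.abline(v = r$lower, col = "blue")
          if (r$upper != r$lower)
            lattice::panel.abline(v = r$upper, col = "blue")
        }
      }
    })
  obj <- structure(list(kind = "parameter_cis", data = ci_table,
                        reference_lines = refs, level = level,
                        trellis = tr),
                   class = "pm_plot")
  if (!is.null(out)) .render_plot(obj, out)
  invisible(obj)
}

.render_plot <- function(obj, out) {
  ext <- tolower(tools::file_ext(out))
  dev <- switch(ext,
    pdf = function() grDevices::pdf(out, width = 10, height = 8),
    svg = function() grDevices::svg(out, width = 10, height = 8),
    png = function() grDevices::png(out, width = 1200, height = 960),
    stop("unsupported format: ", ext, call. = FALSE))
  dev()
  on.exit(grDevices::dev.off())
  print(obj$trellis)
  invisible(out)
}

#' @export
print.pm_plot <- function(x, ...) {
  print(x$trellis)
  invisible(x)
}
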