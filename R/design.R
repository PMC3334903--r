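#' Factorial PM experiment designs
#'
#' Describes the factor structure of a PM experiment: strains x biological
#' replicates x technical replicates x 96 wells, optionally crossed with a
#' set of cultivation durations (inoculum ages). Technical replicate counts
#' may vary per cultivation duration (e.g. a final long duration repeated
#' only twice).
#'
#' @param strains Character vector of strain ids (or a count).
#' @param biological_replicates Number of biological replicates.
#' @param technical_replicates Number of technical replicates; either a single
#'   count or, when `cultivation_durations` is given, a vector with one count
#'   per duration.
#' @param cultivation_durations Optional numeric vector of inoculum
#'   cultivation durations in hours.
#' @param wells_per_plate Number of wells per plate (96).
#' @return An object of class `pm_design`.
#' @examples
#' d1 <- pm_design(strains = 4, biological_replicates = 2,
#'                 technical_replicates = 10)
#' n_curves(d1)  # 7680
#' @export
pm_design <- function(strains, biological_replicates = 1L,
                      technical_replicates = 1L,
                      cultivation_durations = NULL,
                      wells_per_plate = 96L) {
  if (is.numeric(strains) && length(strains) == 1L)
    strains <- sprintf("strain%02d", seq_len(strains))
  strains <- as.character(strains)
  if (!length(strains)) stop("need at least one strain", call. = FALSE)
  if (wells_per_plate < 1L) stop("zero wells per plate", call. = FALSE)
  if (biological_replicates < 1L || any(technical_replicates < 1L))
    stop("replicate counts must be positive", call. = FALSE)
  if (!is.null(cultivation_durations)) {
    nd <- length(cultivation_durations)
    if (length(technical_replicates) == 1L)
      technical_replicates <- rep(technical_replicates, nd)
    if (length(technical_replicates) != nd)
      stop("technical_replicates must match cultivation_durations",
           call. = FALSE)
  } else if (length(technical_replicates) != 1L) {
    stop("vector technical_replicates requires cultivation_durations",
         call. = FALSE)
  }
  structure(list(strains = strains,
                 biological_replicates = as.integer(biological_replicates),
                 technical_replicates = as.integer(technical_replicates),
                 cultivation_durations = cultivation_durations,
                 wells_per_plate = as.integer(wells_per_plate)),
            class = "pm_design")
}

#' @export
print.pm_design <- function(x, ...) {
  cat(sprintf("<pm_design> %d strain(s) x %d biological x %s technical, %d wells\n",
              length(x$strains), x$biological_replicates,
              paste(x$technical_replicates, collapse = "/"),
              x$wells_per_plate))
  if (!is.null(x$cultivation_durations))
    cat("  cultivation durations [h]:",
        paste(x$cultivation_durations, collapse = ", "), "\n")
  cat(sprintf("  %d plates, %d curves\n", n_plates(x), n_curves(x)))
  invisible(x)
}

#' Enumerate curve slots of a design
#'
#' Expands a design into one row per curve slot (strain x biological
#' replicate x cultivation duration x technical replicate x well) in a fixed,
#' deterministic order. The row count always equals the closed-form
#' product/sum of the design.
#'
#' @param design A `pm_design`.
#' @return A data frame with columns `strain`, `biol_rep`, `cultivation`,
#'   `tech_rep`, `plate`, `well`.
#' @export
build_design <- function(design) {
  stopifnot(inherits(design, "pm_design"))
  durations <- design$cultivation_durations
  if (is.null(durations)) durations <- NA_real_
  cells <- expand.grid(
    tech_rep = seq_len(max(design$technical_replicates)),
    d_idx = seq_along(durations),
    biol_rep = seq_len(design$biological_replicates),
    strain = design$strains,
    stringsAsFactors = FALSE)
  tr <- design$technical_replicates
  keep <- cells$tech_rep <= tr[pmin(cells$d_idx, length(tr))]
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$strain, cells$biol_rep, cells$d_idx,
                       cells$tech_rep), , drop = FALSE]
  cells$cultivation <- durations[cells$d_idx]
  cells$plate <- sprintf("%s_b%d_d%d_t%d", cells$strain, cells$biol_rep,
                         cells$d_idx, cells$tech_rep)
  wells <- well_labels()[seq_len(design$wells_per_plate)]
  out <- cells[rep(seq_len(nrow(cells)), each = length(wells)),
               c("strain", "biol_rep", "cultivation", "tech_rep", "plate")]
  out$well <- rep(wells, nrow(cells))
  rownames(out) <- NULL
  out
}

#' @rdname build_design
#' @export
n_plates <- function(design) {
  stopifnot(inherits(design, "pm_design"))
  length(design$strains) * design$biological_replicates *
    sum(design$technical_replicates)
}

#' @rdname build_design
#' @export
n_curves <- function(design) n_plates(design) * design$wells_per_plate

#' @rdname build_design
#' @details `n_replicate_groups()` counts the replicate groups of a design:
#'   one group per strain x biological replicate x cultivation duration x
#'   well, i.e. technical replicates are the group members.
#' @export
n_replicate_groups <- function(design) {
  stopifnot(inherits(design, "pm_design"))
  nd <- max(1L, length(design$cultivation_durations))
  length(design$strains) * design$biological_replicates * nd *
    design$wells_per_plate
}

#' Preset designs of the three study datasets
#'
#' `design_two_species()` is the two-species benchmark: four strains (two
#' *E. coli*, two *P. aeruginosa*) x ten technical replicates per biological
#' replicate x 96 wells; with `biological_replicates = 2` (both measurement
#' campaigns pooled) it yields 7680 curves, a single campaign yields 3840.
#' `design_cultivation_time()` is the inoculum-age series: one *E. coli* K12
#' strain grown for nine durations, four technical replicates each except the
#' last (two), yielding 3072 + 192 = 3264 curves and 864 replicate groups.
#'
#' @param biological_replicates Number of pooled biological replicates.
#' @return A `pm_design`.
#' @export
design_two_species <- function(biological_replicates = 2L) {
  pm_design(strains = c("EcoliDSM30083", "EcoliK12", "Paer1707", "Paer429SC"),
            biological_replicates = biological_replicates,
            technical_replicates = 10L)
}

#' @rdname design_two_species
#' @export
design_cultivation_time <- function() {
  pm_design(strains = "EcoliK12",
            cultivation_durations = c(16.75, 18.00, 19.33, 20.50, 21.92,
                                      23.25, 24.50, 25.58, 40.33),
            technical_replicates = c(rep(4L, 8L), 2L))
}
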