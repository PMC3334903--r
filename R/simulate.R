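#' Shape specifications for synthetic respiration curves
#'
#' Describes the true underlying curve of one well for the synthetic-data
#' generator. Families cover the curve-shape taxonomy seen in real PM data:
#' the four sigmoid growth models; `biphasic` (sum of two logistic phases: a
#' steep primary ascent, an interim plateau, then a shallower second ascent);
#' `linear_drift` (an intrinsically negative reaction with a slight linear
#' colour drift); and `flat` (constant baseline). Gaussian noise is added and
#' the result truncated to the instrument range [0, cap]. Optional artifact
#' injection adds a single-sample spike and/or a transient dip.
#'
#' @param family Shape family name.
#' @param A,mu,lambda Primary-phase parameters (units, units/h, h).
#' @param nu Richards shape exponent.
#' @param alpha,t_shift Modified-Gompertz extras.
#' @param A2,mu2,lambda2 Second-phase parameters for `biphasic`.
#' @param baseline Baseline level in units (flat / drift families).
#' @param drift Linear drift slope in units/h.
#' @param noise_sd Gaussian noise standard deviation in units.
#' @param noise_df If finite, noise is heavier-tailed: scaled Student t with
#'   this many degrees of freedom.
#' @param spike,dip Logical artifact-injection flags.
#' @param spike_height Spike excursion in units.
#' @param dip_depth,dip_length Depth (units) and length (readings) of a dip.
#' @param cap Instrument cap (units).
#' @return An object of class `pm_shape_spec`.
#' @examples
#' shape_spec("biphasic", A = 150, mu = 40, lambda = 5,
#'            A2 = 100, mu2 = 8, lambda2 = 45)
#' @export
shape_spec <- function(family = c("logistic", "gompertz", "gompertz_exp",
                                  "richards", "biphasic", "linear_drift",
                                  "flat"),
                       A = 250, mu = 15, lambda = 8, nu = 2,
                       alpha = 0.01, t_shift = 91,
                       A2 = 100, mu2 = 5, lambda2 = 50,
                       baseline = 10, drift = 0.3,
                       noise_sd = 5, noise_df = Inf,
                       spike = FALSE, dip = FALSE,
                       spike_height = 60, dip_depth = 30, dip_length = 5L,
                       cap = 400) {
  family <- match.arg(family)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  tot <- switch(family, biphasic = A + A2, linear_drift = baseline,
                flat = baseline, A)
  if (tot > cap)
    stop("shape exceeds the instrument cap of ", cap, " units", call. = FALSE)
  structure(as.list(environment()), class = "pm_shape_spec")
}

#' Deterministic (noise-free) value of a shape spec
#'
#' @param shape A `pm_shape_spec`.
#' @param times Times in hours.
#' @return Expected curve values in units.
#' @export
shape_value <- function(shape, times) {
  stopifnot(inherits(shape, "pm_shape_spec"))
  with(shape, switch(family,
    logistic = ,
    gompertz = growth_model_value(family, times,
                                  c(A = A, mu = mu, lambda = lambda)),
    gompertz_exp = growth_model_value(family, times,
      c(A = A, mu = mu, lambda = lambda, alpha = alpha, t_shift = t_shift)),
    richards = growth_model_value(family, times,
      c(A = A, mu = mu, lambda = lambda, nu = nu)),
    biphasic =
      growth_model_value("logistic", times, c(A = A, mu = mu, lambda = lambda)) +
      growth_model_value("logistic", times, c(A = A2, mu = mu2, lambda = lambda2)),
    linear_drift = baseline + drift * times,
    flat = rep(baseline, length(times))))
}

#' Default measurement grid of the instrument
#'
#' Readings every 15 minutes over 91 hours: 365 time points.
#' @return Numeric vector of times in hours.
#' @export
default_time_grid <- function() seq(0, 91, by = 0.25)

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one kinetic curve
#'
#' Adds i.i.d. noise to the shape's expected curve, injects any requested
#' artifacts, and truncates to the instrument range [0, cap]. With a fixed
#' seed the output is reproducible bit for bit; the caller's RNG state is
#' left untouched when a seed is given.
#'
#' @param shape A `pm_shape_spec`.
#' @param times Measurement times in hours (default: 15-min grid over 91 h).
#' @param seed Optional integer seed.
#' @param well,strain,biol_rep,tech_rep,cultivation,substrate Curve metadata.
#' @return A `pm_curve`.
#' @export
simulate_curve <- function(shape, times = default_time_grid(), seed = NULL,
                           well = "A01", strain = NA_character_,
                           biol_rep = NA_character_, tech_rep = NA_character_,
                           cultivation = NA_real_, substrate = NA_character_) {
  stopifnot(inherits(shape, "pm_shape_spec"))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  mean_y <- shape_value(shape, times)
  n <- length(times)
  y <- .with_seed(seed, {
    noise <- if (shape$noise_sd == 0) numeric(n)
      else if (is.finite(shape$noise_df))
        shape$noise_sd * stats::rt(n, df = shape$noise_df) /
          sqrt(shape$noise_df / (shape$noise_df - 2))
      else stats::rnorm(n, 0, shape$noise_sd)
    out <- mean_y + noise
    if (shape$spike && n >= 3L) {
      i <- sample(2:(n - 1L), 1L)
      out[i] <- out[i] + shape$spike_height
    }
    if (shape$dip && n >= shape$dip_length + 2L) {
      i <- sample(seq_len(n - shape$dip_length - 1L) + 1L, 1L)
      idx <- i:(i + shape$dip_length - 1L)
      out[idx] <- out[idx] - shape$dip_depth
    }
    out
  })
  y <- pmin(pmax(y, 0), shape$cap)
  pm_curve(times, y, well = well, strain = strain, biol_rep = biol_rep,
           tech_rep = tech_rep, cultivation = cultivation,
           substrate = substrate)
}

#' Default shape-assignment policy
#'
#' Maps each (strain, well) pair to a fixed `pm_shape_spec`, emulating the
#' composition observed in real GEN III runs: roughly 55% sigmoid positives
#' (logistic/Gompertz/Richards with varying parameters), 10% biphasic
#' positives, 25% near-flat negatives with slight linear drift, 10% flat
#' negatives; about 5% of wells carry a spike artifact and 5% a dip. Well A01
#' (the substrate-free control) is always a drift negative. The assignment is
#' a pure function of (`seed`, strain, well): technical and biological
#' replicates of a well share their true shape and differ only in noise.
#'
#' @param seed Integer seed fixing the assignment.
#' @param noise_sd Noise level passed to every shape (units).
#' @return A function `(strain, well) -> pm_shape_spec`.
#' @export
default_shape_policy <- function(seed = 1L, noise_sd = 5) {
  force(seed); force(noise_sd)
  function(strain, well) {
    key <- sum(utf8ToInt(paste(strain, well, sep = "/")) *
                 seq_along(utf8ToInt(paste(strain, well, sep = "/"))))
    .with_seed((as.numeric(seed) * 7919 + key) %% 2147483647, {
      u <- stats::runif(1)
      spike <- stats::runif(1) < 0.05
      dip <- stats::runif(1) < 0.05
      if (well == "A01") u <- 0.999  # control well: drift negative
      if (u < 0.20) {
        shape_spec("logistic", A = stats::runif(1, 150, 380),
                   mu = stats::runif(1, 5, 30),
                   lambda = stats::runif(1, 2, 20),
                   noise_sd = noise_sd, spike = spike, dip = dip)
      } else if (u < 0.40) {
        shape_spec("gompertz", A = stats::runif(1, 150, 380),
                   mu = stats::runif(1, 5, 30),
                   lambda = stats::runif(1, 2, 20),
                   noise_sd = noise_sd, spike = spike, dip = dip)
      } else if (u < 0.55) {
        shape_spec("richards", A = stats::runif(1, 150, 380),
                   mu = stats::runif(1, 5, 30),
                   lambda = stats::runif(1, 2, 20),
                   nu = stats::runif(1, 0.5, 4),
                   noise_sd = noise_sd, spike = spike, dip = dip)
      } else if (u < 0.65) {
        A1 <- stats::runif(1, 100, 200)
        shape_spec("biphasic", A = A1, mu = stats::runif(1, 20, 50),
                   lambda = stats::runif(1, 2, 10),
                   A2 = stats::runif(1, 50, 380 - A1),
                   mu2 = stats::runif(1, 3, 10),
                   lambda2 = stats::runif(1, 40, 70),
                   noise_sd = noise_sd, spike = spike, dip = dip)
      } else if (u < 0.90) {
        shape_spec("linear_drift", baseline = stats::runif(1, 5, 30),
                   drift = stats::runif(1, 0.05, 0.6),
                   noise_sd = noise_sd, spike = spike, dip = dip)
      } else {
        shape_spec("flat", baseline = stats::runif(1, 5, 40),
                   noise_sd = noise_sd, spike = spike, dip = dip)
      }
    })
  }
}

#' Simulate a full factorial PM experiment
#'
#' Generates one plate per design cell x technical replicate. The true shape
#' of each well comes from `policy(strain, well)`; replicate curves share the
#' shape and differ only in independent noise. With identical (design,
#' policy, seed) the result is reproducible bit for bit.
#'
#' @param design A `pm_design`.
#' @param policy A function `(strain, well) -> pm_shape_spec` (default:
#'   [default_shape_policy()] seeded from `seed`), or a named list keyed by
#'   `strain/well`.
#' @param seed Integer seed.
#' @param times Measurement grid in hours.
#' @param dataset_id Dataset identifier stamped on the plates.
#' @return A list of `pm_plate` objects, ordered as in [build_design()].
#' @examples
#' plates <- simulate_experiment(pm_design(strains = 2), seed = 42)
#' length(plates)
#' @export
simulate_experiment <- function(design, policy = NULL, seed = 1L,
                                times = default_time_grid(),
                                dataset_id = "synthetic") {
  stopifnot(inherits(design, "pm_design"))
  if (is.null(policy)) policy <- default_shape_policy(seed)
  get_shape <- if (is.function(policy)) policy else function(strain, well) {
    key <- paste(strain, well, sep = "/")
    if (is.null(policy[[key]]))
      stop("policy has no shape for ", key, call. = FALSE)
    policy[[key]]
  }
  slots <- build_design(design)
  plates_meta <- unique(slots[, c("strain", "biol_rep", "cultivation",
                                  "tech_rep", "plate")])
  wells <- well_labels()[seq_len(design$wells_per_plate)]
  .with_seed(seed, {
    lapply(seq_len(nrow(plates_meta)), function(i) {
      pm <- plates_meta[i, ]
      curves <- lapply(wells, function(w) {
        simulate_curve(get_shape(pm$strain, w), times = times, seed = NULL,
                       well = w, strain = pm$strain,
                       biol_rep = as.character(pm$biol_rep),
                       tech_rep = as.character(pm$tech_rep),
                       cultivation = pm$cultivation)
      })
      pm_plate(curves, plate_id = pm$plate, dataset_id = dataset_id)
    })
  })
}
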