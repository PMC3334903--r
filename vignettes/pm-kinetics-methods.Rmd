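---
title: "Estimating and comparing curve parameters from Phenotype MicroArray kinetics"
author: "pmkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing curve parameters from Phenotype MicroArray kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 5)
library(pmkin)
```

## The measurement and its parameters

A Phenotype MicroArray (PM) instrument records cellular respiration as
colour formation of a tetrazolium dye, every 15 minutes, in 96 wells per
plate, each well presenting a different substrate or condition. Over a run
of ~91 h this yields one kinetic curve of up to 365 readings per well, in
arbitrary "OmniLog units" that the instrument caps at 400. In analogy to
classical growth curves, four parameters summarise a curve:

* **λ (lag phase, h)** — how long the signal stays near baseline before the
  main ascent;
* **μ (maximum slope, units/h)** — the steepest rate of signal increase;
* **A (maximum height, units)** — the plateau the signal reaches;
* **AUC (area under the curve)** — an aggregate of height and timing.

`pmkin` implements three estimators of these parameters behind one fitting
front end, `pm_fit(curve, method = c("spline", "model", "native"))`, plus
bootstrap confidence intervals, CI-based comparison machinery, archetypal
classification of curve shapes, plate-level graphics and a synthetic-data
generator that reproduces the factorial structure of real PM experiments.

## The three estimators

**Native algorithm** (`native_parameters()`). The instrument's own
parametric analysis uses a handful of order statistics: the maximum height
is the 10th-percentile-highest reading, the baseline the 12th-smallest
among the first 48 readings, and λ and μ follow from the first crossing
times of the 15%, 50% and 85% levels between the two. The AUC is the plain
sum of all readings (a step-function convention in units × readings). The
method uses only a few data points, provides no confidence intervals, and
assumes a shape symmetric around its inflection; all of these limitations
motivate the fitted alternatives. Two phrasings of the published definition
are ambiguous and are exposed as explicit options rather than silently
decided: `max_rule` chooses between the nearest-rank 90th percentile
(default) and the literal 10th-highest reading, and the slope is the total
rise over each of the two half-windows (excluding the mid-crossing reading
itself) divided by the spanned time — the reading-index convention for
"one before/after" is one sampling index, since the algorithm operates on
discrete reads. Curves that never cross their mid-level (flat negatives)
get `NA` for λ and μ with a flag; A and AUC are always returned.

**Growth-model fits** (`fit_growth_model()`, `select_best_model()`). Four
standard sigmoid models — logistic, Gompertz, modified Gompertz and
Richards — are written in the re-parameterisation in which (A, μ, λ) appear
directly as model parameters, and fitted by bounded Levenberg–Marquardt
nonlinear least squares (via minpack.lm). For Gaussian errors the model
comparison uses `AIC = n ln(RSS/n) + 2(p + 1)`; the lowest AIC wins, ties
go to fewer parameters, then to the fixed candidate order, so a Richards
fit that merely reproduces a logistic curve (ν = 1) loses to the logistic
by its penalty. Two numerical choices matter:

* *Starting values* are heuristic but noise-robust: the initial slope is the
  maximum difference quotient over a window of ~2.5% of the series rather
  than between adjacent readings, because at 15-minute sampling the
  adjacent-reading quotient is dominated by noise.
* *Identifiability bounds*: for the modified Gompertz the secondary-rise
  shift time is constrained to the observed window and its rate to [0, 1].
  Unconstrained, the secondary term can be driven to zero by sending the
  shift time past the window, which collapses the model onto the plain
  Gompertz with two unidentifiable parameters — and lets it win model
  selection by pure noise-chasing. A small deterministic multi-start on the
  shift time avoids boundary traps.

Non-convergence is a regular, recorded outcome ("without fittable models"),
not an exception. Implausible estimates — λ < 0, A > 400 — are *never*
clamped; they are preserved and flagged, so downstream accounting
(`fit_accounting()`) can report them the way reliability tables do.

**Smoothing spline** (`fit_spline()`), the recommended default. A cubic
smoothing spline (`stats::smooth.spline`, smoothness chosen by generalized
cross-validation unless a `spar` is given) is fitted to the raw readings;
A is the maximum of the fitted spline, μ the maximum of its first
derivative on a dense uniform grid (10× the observation density, earliest
argmax on ties), and the tangent at that point, `y(t) = μ(t − λ)`, yields
the lag via `λ = t_μ − y_μ/μ`, which makes the tangent identity
`y_μ = μ(t_μ − λ)` hold to machine precision by construction. AUC is the
composite-trapezoid integral of the fitted spline. The spline path is
*total*: every finite curve with ≥ 4 distinct time points yields a full
parameter set, including flat negatives, biphasic curves and
artifact-laden series, which is precisely its practical advantage over the
model path. On essentially flat fits (maximum derivative below a floor of
1e-8 units/h) the tangent construction is refused and λ flagged rather than
returned as a numerically meaningless ratio. Because a smoothing spline
shrinks toward the data, A cannot materially overshoot the observed range,
so capped data keep A ≤ 400 — unlike model extrapolation.

Smoothing-parameter choice is the critical step of this method: heavier
smoothing biases μ downward; lighter smoothing overfits flat negatives and
inflates μ and the width of λ's intervals. GCV is the package default, and
an explicit override is supported for sensitivity analysis.

## Uncertainty and comparisons

`bootstrap_cis()` implements a nonparametric pairs bootstrap: observation
pairs are resampled with replacement (tied times are merged with
multiplicity weights, which reproduces the duplicated-data fit exactly),
the curve is refitted, parameters re-extracted on the *original* time
window, and percentile intervals formed (default level 0.95, B = 100,
seeded). Refit failures are dropped and counted; more than 50% failures
flags the interval unreliable. For the model method, the family selected on
the full data is held fixed across resamples so the intervals measure
estimation uncertainty, not model-selection churn. A point estimate outside
its own percentile interval is flagged, never reordered. Deliberately, no
multiplicity adjustment is applied in this per-curve workflow: the intent
is to surface all potentially interesting differences.

Two intervals for the same parameter are compared as closed intervals
(`ci_overlap()`): overlap (shared endpoints included — the conservative
convention) means no detectable difference; disjoint intervals are a
detectable difference whose **minimum expectable magnitude** is the gap
between the nearer opposite limits, signed by direction.

For groups of replicate curves, `group_mean_cis()` averages member points
and member limits — a quick, deliberately informal display device, not a
valid test. Test decisions come from `simultaneous_mean_differences()`: a
one-way layout on per-curve point estimates, user-defined contrasts of
group means (helpers: all pairs, versus control), pooled error variance,
and a max-|t| critical value for the joint multivariate t implied by the
contrast correlation structure, computed by seeded Monte Carlo (1e5 draws;
Bonferroni fallback on degenerate correlation matrices). A single contrast
reduces exactly to the classical pooled t interval; simultaneous intervals
are never narrower than unadjusted ones; an interval excluding zero flags
a detectable group difference.

## Classifying curve shapes

Post-processing starts from the parameter table. A threshold of 100 units
on A — partially arbitrary, and exposed as an argument — dichotomises
reactions into positive (strictly above) and negative. Beyond the
dichotomy, `fit_archetypes()` represents curves as convex combinations of a
few extreme *archetypes* in (λ, μ, A, AUC) space: alternating convex least
squares minimises ‖X − CZ‖² with coefficient rows on the simplex and each
archetype itself a convex combination of data rows. The small simplex-
constrained subproblems are solved as non-negative least squares with a
sum-to-one penalty row (Lawson–Hanson active set on the shared Gram matrix
for the coefficient step; `pracma::lsqnonneg` for the archetype step),
followed by exact renormalisation so simplex constraints hold to 1e-8.
Archetype updates that would increase the RSS are rejected, making the RSS
trace non-increasing by construction. Columns are standardised before
fitting (the parameters live on wildly different scales — hours versus
unit-hours) and archetypes are reported back in original units.

Because spline lag estimates of intrinsically negative reactions can be
extreme negative outliers, `truncate_lambda()` symmetrises the λ column
before archetype analysis by clamping values below −max(λ) to −max(λ).

`step_archetypes_elbow()` fits k = 1…10 with five random restarts each and
picks k by the elbow criterion: the k whose RSS improvement is largest
*compared with the subsequent improvement*, i.e. k maximising
drop(k) − drop(k+1) with drop(k) = RSS(k−1) − RSS(k). We use this falloff
form rather than "the largest drop that dominates all later drops" because
the latter degenerates on clean cluster structure: for three equally sized
tight clusters at triangle vertices, drop(2) ≈ drop(3), and noise decides —
whereas the falloff form reliably identifies the last big step before the
scree flattens. Ties go to the smaller k. Rank correlations between
parameters within and across methods (`parameter_correlations()`, Spearman
and Kendall, chosen because the estimates are neither normal nor linearly
related) complete the post-processing toolkit.

## The synthetic-data generator

Real PM raw data are large and instrument-bound, so the package carries a
first-class generator. `pm_design()` describes the factorial structure —
strains × biological replicates × technical replicates × 96 wells,
optionally crossed with inoculum cultivation durations with per-duration
replicate counts — and two presets reproduce the reference designs: the
two-species benchmark (4 strains × 10 technical replicates × 96 wells,
3840 curves per campaign, 7680 pooled over two) and the cultivation-time
series (9 durations × 4 technical replicates, the longest duration twice,
3264 curves, 864 replicate groups).

`simulate_curve()` adds i.i.d. Gaussian noise (default sd 5 units, a
Student-t option for heavier tails) to a deterministic shape and truncates
to the instrument range [0, 400]. The shape families cover the taxonomy
seen in real plates: the four sigmoid models; *biphasic* curves built as
the sum of two logistic phases (steep primary ascent, interim plateau,
shallower second ascent); *linear-drift* negatives (no respiration, slight
colour drift); *flat* negatives; plus optional injected artifacts (a
single-reading spike, a transient dip). The default measurement grid is
0–91 h in 0.25 h steps (365 readings). The default noise level of 5 units
on signals of 150–400 units was chosen once as a realistic mid-range
between the visually almost noise-free positives and the noisier flat
negatives of real runs; it is a config argument, not a constant.

`default_shape_policy()` maps each (strain, well) pair deterministically
to a shape — roughly 55% sigmoid positives, 10% biphasic, 35% negatives,
with ~5% spike and ~5% dip contamination, and the substrate-free control
well A01 always a drift negative — so technical and biological replicates
share a true shape and differ only in noise, exactly as replicates should.
What the generator does *not* emulate: autocorrelated measurement noise,
plate-position or edge effects, batch drift between campaigns, and
chemistry-level artifacts such as abiotic dye conversion. Tests passing on
synthetic plates therefore validate the estimation and comparison
machinery, not the biology of any particular organism.

Negative-control subtraction (A01 from all other wells) is implemented
(`subtract_control()`) but off by default and not used anywhere in the
package's own workflows: control wells can show reproducible strain-
specific signal larger than genuine negatives on the same plate, so
treating them as an additive error term is unsafe; raw curves are the
recommended basis for fitting.

## Numerical choices and degenerate inputs

* Missing (time, value) pairs are dropped pairwise; a curve with fewer than
  4 remaining points is unfittable by every method.
* Series shorter than 48 readings flag the native baseline; shorter than
  12, the baseline falls back to the plain minimum (the published rank is
  undefined there).
* `smooth.spline` failures (possible only on pathological inputs) fall back
  to a fixed `spar`, then to an exact least-squares line, so spline
  totality holds on anything finite.
* AIC uses `max(RSS, 1e-300)` to stay finite on interpolating fits.
* The bootstrap reports intervals from however many resamples succeeded
  (with the count); it never re-sorts a point estimate into its interval.
* Archetype restarts derive their seeds deterministically from the master
  seed; identical seeds give identical scree curves.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script work at the scale of one full
synthetic campaign (3840 spline fits), a 768-curve subsample for the
four-model path, 1000 random curves for the native-algorithm oracle, 200
Monte-Carlo repetitions for bootstrap coverage (B = 100) and for the
familywise error of the simultaneous comparisons, and 300-point planted
data for archetype recovery. These sizes give stable rates (binomial
standard errors ≤ 2 percentage points on the coverage estimates) while
keeping a full run in minutes.

## A worked example

```{r example}
plates <- simulate_experiment(pm_design(strains = c("K12", "DSM30083")),
                              seed = 11)
cv <- plates[[1]][["G11"]]
fit <- pm_fit(cv, "spline")
coef(fit)

ci <- bootstrap_cis(cv, "spline", B = 100, seed = 1)
ci$table
```

```{r plots, eval = FALSE}
plot_plate_grid(plates, group_by = "strain", out = "grid.pdf")
plot_levelmap(plates[1:2], out = "levelmap.pdf")
```

## Known limitations

* Model-fit failure *rates* on real data depend on optimizer internals and
  are not a reproduction target; only the flagging and accounting mechanics
  are contractual.
* The spline's A estimator is mildly positively biased on long plateaus
  (the maximum of a smoothed noisy series); its percentile bootstrap
  interval for A inherits that bias. For coverage-critical work on curves
  whose family is known, the model path is preferable.
* No joint spline across replicate bundles, no monotone or shape-
  constrained spline variants, no mixed-effects decomposition of technical
  versus biological variance, and no global multiple-testing layer — all
  natural extensions, all out of scope here.
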