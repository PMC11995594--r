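---
title: "Methods: habitat models for central-place foragers"
author: "cpfhabitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat models for central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The modelling problem

A central-place forager breeding on an island makes multi-day trips to sea
and returns to the same rookery. Telemetry gives presences only; to fit a
classifier one needs pseudo-absences that answer "where could this animal
have been, given how it moves and where it must return?" The pipeline
couples three ingredients:

* a **null movement model** per trip — a first-order vector-autoregressive
  (VAR) process on hourly step vectors, rookery-pinned, which preserves each
  trip's speed, duration and central-place constraint while erasing its
  environmental preference;
* an **exclusion filter** that removes simulated positions too close in
  space and time to any observed presence (same or adjacent ~10-km grid
  cell within ±6 days, the window chosen to match the weekly averaging of
  the environmental archive);
* replicate **random-forest classifiers** on exactly balanced
  presence/absence datasets, evaluated with trip-grouped cross-validation
  so that autocorrelated points from one trip can never straddle the
  train/test boundary.

Suitability maps follow from predicting every weekly environmental field in
July–October, averaging over replicates and weeks, and thresholding the
hindcast mean at its upper quartile ("core habitat"). Projections reuse the
hindcast thresholds after a delta-change bias correction, and ExDet
diagnostics say where the projected covariates leave the support of the
training data.

## The synthetic world

The generator's defaults are the stated world of the test suite; they were
fixed once, for realism, and are not tuned against test outcomes.

* **Grid**: 56 x 64 cells of 0.18 degrees lon x 0.09 degrees lat (~10 km at 57 N),
  cell-center registration, WGS-84, haversine distances with R = 6371 km.
  Indexing is 1-based (row = latitude, column = longitude), the natural R
  convention.
* **Bathymetry**: monotone from ~20 m at the eastern edge to ~3000 m at the
  western edge through a sigmoidal shelf break; shelf = depth <= 200 m. A
  "true" bathymetry equal to 0.85x the model bathymetry defines the
  mismatch mask (model says basin, truth says shelf), emulating regridding
  error along the slope.
* **Weekly fields** (52-week calendar, week 1 starting Jan 1): smooth
  deterministic bases plus kernel-smoothed Gaussian noise (smoothing length
  3 cells; sd 0.6 degC for temperatures, 40/25/20 mg C m^-2 for the three
  biomass fields). Bottom temperature increases with depth — which makes it
  collinear with bathymetry over the basin (|r| > 0.7 in sampled data, so
  the screen drops bathymetry there) but not over the shelf. A Gaussian
  cold anomaly on the northern mid-shelf keeps a contiguous patch below
  2 degC (the cold pool). Depth-integrated biomass peaks along the shelf
  break (a "green belt") rather than monotonically with depth, and each
  biomass field receives per-year regional anomalies whose spatial pattern
  evolves between spring and summer — without this interannual structure
  the Apr–Jul mean phytoplankton field degenerates into a low-noise proxy
  for depth and absorbs importance that belongs to the dynamic variables.
* **Trips**: durations are truncated normal with mean 6.6 d and sd 2.4 d
  (minimum 1 d), matching reported fur-seal summaries; hourly steps follow
  a per-component AR(1) with stationary mean step length 4.5 km and
  coefficient 0.75, giving realistic trip extents of tens to a few hundred
  km. Departures are uniform over July–September of uniformly drawn archive
  years. Two rookery complexes sit on the outer shelf at the cell nearest
  70 m depth.
* **Scale of the stated world**: the acceptance-scale experiments use 40
  animals x 3 trips over a 27-year archive. The year span matters: the
  exclusion filter compares candidates against *all* presences, so packing
  many trips into few years saturates the space-time neighbourhood of the
  rookery and displaces pseudo-absences outward, which a classifier can
  detect. At the multi-decade density of a real telemetry program this
  artifact is small (null AUC ~0.51–0.56, inside the accepted 0.43–0.57
  band); in deliberately tiny demo worlds it is visible (README example).

### Endpoint pinning: two mechanisms, deliberately

The *track generator* pins trips with a bridge: at hour `t` a homing drift
`(rookery − position) / (steps remaining)` is added to the AR proposal, and
the residual closure error (one innovation in size) is removed uniformly at
the end. Selection is imposed by weighted resampling among `n_candidates`
proposed steps, with weights `(prod of piecewise-linear preferences)^strength`;
strength 0 reduces exactly to the unweighted bridge.

The *pseudo-absence simulator* instead pins by post-hoc drift subtraction:
free VAR simulation, then `closure error / n_steps` subtracted from every
step. This is second-order faithful to the fitted VAR and exactly testable
(endpoints match to machine precision). We did not use drift subtraction in
the selecting generator because removing a large closure drift after the
fact translates the whole realized path and destroys the very association
with covariates the selection created; the bridge keeps selection local
while preserving the AR step structure (lag-1 autocorrelation of realized
steps stays within 0.1 of the nominal coefficient, which the tests check).
Candidates whose mean step length is outside a factor two of the trip's are
re-simulated (at most 20 rounds) and otherwise flagged, a concrete reading
of "resembles the original track with respect to speed".

### Exclusion filter conventions

"Adjacent" is read as the 8-neighbour (queen) cells — the conservative
choice, removing more. The six-day window is symmetric,
`|candidate date − presence date| <= 6`. Candidates are filtered against
the presence points of *all* trips (the stricter reading); the window makes
cross-year comparisons vacuous automatically.

### Replicate assembly

Per replicate: one presence per trip-day drawn uniformly; the partner track
is the surviving candidate with the most distinct days (ties to the lowest
index) for replicate 1, and successive items of a seeded permutation of the
remaining eligible candidates for later replicates; both members are
down-sampled to one position per day; days present in only one member are
dropped from both, *within habitat*, so each habitat's dataset is exactly
1:1. Consequently the replicate-1 dataset is systematically the largest
(the maximal-day partner is also the most filter-displaced candidate), a
property worth knowing when comparing replicates.

## Modelling choices

* The classifier is a bagged CART forest with Gini splitting, 500 trees,
  minimum node size 1 and tuned `mtry` in {2, 3, 4}. No random-forest
  package exists in the supported environment, so the learner is compiled
  into the package; its behaviour is pinned by tests (exact AUC oracles,
  separable data, permutation nulls, determinism under seeds).
* Cross-validated performance is the **pooled** out-of-fold AUC (one AUC
  over all held-out predictions), not the mean of per-fold AUCs — robust to
  small folds; with trip-grouped folds some folds can be tiny.
* Fold balancing is greedy: trips (or years, for the temporal metric)
  placed largest-first into the smallest fold. The resulting imbalance is
  bounded by the largest group size.
* Collinearity screening computes pairwise Pearson r on the pooled
  replicate rows; for |r| > 0.7 the static variable loses to the dynamic
  one (bathymetry loses to bottom temperature over the basin), and between
  two dynamic variables the later one in the canonical variable order is
  dropped. All flagged pairs are reported.
* Scaled importance maps each replicate's Gini importances linearly onto
  [0, 100]; if all raw importances are equal the scaling is ill-posed and
  every variable receives 50.
* Partial dependence uses a 50-point quantile-spaced grid and, for
  ensembles, a loess smooth (span 0.75) of the replicate-mean curve.

## Prediction and overlap conventions

* Quantiles use linear interpolation between order statistics (R type 7);
  "top 25%" means values >= the 75th percentile, so a constant surface is
  entirely core (boundary semantics) and a continuous one is core on 25% of
  cells within one cell's rounding.
* The threshold is computed *after* the 375-km accessibility crop, i.e.
  over the cells the animals could actually reach; mismatch cells use the
  mean of the shelf and basin thresholds against the blended surface.
* Cell areas use the spherical quadrilateral formula
  `R^2 * dlambda * (sin(phi2) − sin(phi1))`.
* Fine-to-coarse regridding assigns fine cells to the coarse cell
  containing their center; with ~10-km fine cells inside 0.25-degree coarse
  cells the center rule is unbiased and simple. Overlap statistics treat a
  coarse cell as fished if its mean catch is positive.

## Projection conventions

* Bias correction is additive for every variable (weekly climatological
  offset over the shared historical window), with corrected biomass floored
  at zero afterwards; the floor is switchable (`floor_biomass = FALSE`)
  because the raw additive correction has an exact closure property — the
  corrected historical climatology equals the hindcast climatology to
  machine precision — that the tests verify at 1e-10. Whether a ratio
  correction would suit near-zero biomass better is left open; the additive
  form with flooring is the documented default.
* Projected core habitat reuses the hindcast threshold; change metrics are
  mean core suitability, core area, and the haversine distance from the
  rookery to the suitability-weighted center of gravity of core cells.

## Extrapolation diagnostics

NT1 sums the per-variable shortfall below the reference minimum or above
the maximum, scaled by the reference range (0 = inside all ranges). For
points inside all ranges, NT2 is the Mahalanobis distance to the reference
mean divided by the *largest reference* Mahalanobis distance, so NT2 <= 1
within the reference cloud and NT2 > 1 flags novel combinations. The
reference sample is the pooled July–October hindcast (not per-week
references). Singular reference covariances are ridge-regularized with
`eps = 1e-8 * trace / p`; a constant reference column contributes 0 to NT1
when the target equals the constant and −Inf (univariate) otherwise. The
most-influential covariate is the most negative NT1 term (univariate) or
the variable whose removal most reduces the Mahalanobis distance
(combinatorial, leave-one-out). Variables whose extrapolation is an
artifact of near-zero values can be excluded from the class summary by
name.

## What a green test establishes — and what it does not

The synthetic world has known selection structure, so the tests can ask
questions real data cannot: with selection off, the ensemble AUC must be
chance-level; with strong selection for the 75–200 m band and cold bottom
water, the AUC must recover, the two driving variables must take the top-2
scaled importances, and the partial dependence of depth must be elevated
inside the band. Passing these establishes that the pipeline neither
manufactures signal from its own pseudo-absence machinery nor loses a
strong real one.

It does not establish performance on real telemetry: the generator has no
Argos location error, no behavioural modes (transit vs foraging), no
mesoscale eddies or fronts, no tides or ice, and its preference functions
are stationary. The exclusion filter leaves a small systematic displacement
of pseudo-absences away from used areas even at realistic density — visible
as occasional low Kolmogorov–Smirnov p-values for single covariates in
single replicates — which is an inherent property of this class of
pseudo-absence designs, not an implementation artifact; the operative null
guarantee is the chance-level AUC, which holds.

## Numerical and interface notes

* All randomness flows from integer seeds through fixed-label substreams,
  so archives, trip sets and replicate datasets are bit-identical under
  identical seeds and configurations.
* Weekly covariate extraction uses the weekly bin whose center date is
  nearest the point's UTC date, ties to the earlier bin; Apr–Jul means use
  weeks 14–30 and the Jul–Oct prediction season weeks 27–44 of the fixed
  52-week calendar.
* Archives and surfaces are serialized as plain text (long-format CSV with
  JSON headers/sidecars) because no NetCDF or GeoTIFF interface is
  available in the supported environment; variable names and units follow
  the weekly-ocean-model schema (`bathymetry`, `temp_bottom`,
  `temp_surface`, `phl`, `phl_avg`, `ncao_ncas`, `eup`).
* The pipeline configuration is YAML-serializable and validated with
  field-naming errors; the orchestrator writes a manifest (config, seed,
  timings, artifact checksums) and reproduces artifacts bit-identically
  under the same config and seed.
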