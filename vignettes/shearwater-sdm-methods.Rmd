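---
title: "Survey-based distribution models and strip-transect abundance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey-based distribution models and strip-transect abundance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shearwaterSDM)
```

# The problem

Postbreeding Balearic shearwaters (*Puffinus mauretanicus*) — Europe's only
critically endangered seabird — concentrate in the western English Channel
and southern Celtic Sea in autumn. Vessel-based strip-transect surveys
produce three things an analyst needs to combine: a timestamped effort
track, a sparse set of sightings (occupied cells are on the order of 2% of
surveyed cells), and environmental context. This package implements the
full analysis chain on a 1-km² grid: covariate derivation, effort-based
presence/absence construction, two families of species distribution model
(binomial GAMs under constrained AIC selection, and class-balanced random
forest ensembles validated leave-one-year-out), and a strip-transect
density-multiplication abundance estimator. A seeded synthetic-survey
generator with a known suitability surface makes every stage testable.

# Grid and projection

The area of interest (49.491–51.622° N, 6.888–2.003° W) is divided into
square cells of 1 km² in a local equidistant-cylindrical projection centred
on the box: `x = R cos(lat0) Δlon`, `y = R Δlat`. At this extent the
projection's total-area distortion relative to the geodesic area is below
0.01%, which comfortably supports "1-km²" cells and the area of the
prediction polygon; a conformal zone projection would change cell counts by
far less than the sampling noise of any quantity built on them. Cell
membership is half-open (`[x, x+1000) × [y, y+1000)`), ids are row-major
from the south-west corner, and both are deterministic by construction.

# Derived oceanographic covariates

Bathymetry is stored as *elevation* (negative below sea level), so a
positive depth-anomaly residual literally means "shallower than expected".

* **Terrain ruggedness (TRI)** — mean absolute difference between a cell
  and its eight neighbours; edge cells use the neighbours that exist. TRI
  is invariant to adding a constant to the surface.
* **Aspect** — direction of steepest descent in degrees clockwise from
  north, from Horn's 3×3 weighted gradients (one-sided differences at
  edges); flat cells are missing. Aspect is treated as a plain real
  covariate in degrees. This ignores its circularity (0° and 360° are the
  same direction); the smooths fitted to it should be read with that caveat
  in mind.
* **Depth anomaly** — residuals of a Gaussian-family penalized thin-plate
  smooth of elevation over coordinates (basis dimension 60 by default,
  effective complexity set by REML). Because the smooth is penalized, the
  residuals are exactly orthogonal only to the unpenalized null space of
  the smoother (intercept and linear coordinates); the package's tests
  assert exactly that property, not orthogonality to the full fitted
  surface.
* **Stratification index** — the Simpson–Hunter parameter
  `log10(h/u³)` with water depth `h` (m) and maximum depth-averaged current
  speed `u` (m/s). Tidal fronts sit near 1.9 (log10 m⁻² s³); `mixed` /
  `front` / `stratified` classification uses a ±0.1 band around 1.9, since
  an exact-equality front class would be empty on real-valued rasters. In
  the models the index enters as a continuous covariate; the class is
  reporting convenience.

Dynamic layers (SST, salinity, chlorophyll) are averaged over the survey
window cell-by-cell (missing values excluded with a per-cell divisor) and
extracted at cell centres by bilinear interpolation; static layers use the
cell value (cell mean when the environmental grid is finer).

# Effort, labels and the false-absence filter

Effort is the time the vessel spent in each cell: track segments between
consecutive records are split at cell boundaries and their duration
apportioned by length. Records below 0.5 kn are treated as stationary (the
survey protocol's "not stationary" clause gives no number; 0.5 kn separates
drift from steaming on these vessels), and record gaps above 300 s are
treated as off-effort. Sightings map to the cell of the bird's first
observed position and are excluded when the vessel exceeded 17 kn or its
contiguous visit to the cell exceeded 15 min (the visit is the contiguous
run of track records in that cell around the sighting, not the daily
total). Cells with birds are presences; zero-bird cells are absences only
with ≥ 180 s of effort, otherwise "undetermined" and excluded from fitting.
The fraction of zero-sighting cells removed this way is always reported —
on the original surveys it removed about a third of zero cells, and the
pipeline emits the analogous number for any run.

# Binomial GAMs under constrained AIC selection

Each candidate model is a penalized binomial additive model (logit link),
one thin-plate smooth per covariate with basis dimension `k = 4`,
smoothing parameters by REML. Four knots deliberately restrict each
response curve to simple, ecologically interpretable shapes and help
extrapolation. ("Four knots" is read as basis dimension 4; with an
identifiability constraint that is three free functions per smooth.)
Candidate sets obey the collinearity constraints: at most one of
{max current, stratification index}; at most one of {roughness, anomaly,
aspect}; location enters as nothing, distance-to-coast, or latitude +
longitude; fish and oceanographic variables never co-occur, and sea state
is appended to every explanatory model. Fish abundances are log(x+1)
transformed for GAMs (zeros occur) but enter forests untransformed. Models
are ranked by AIC using effective degrees of freedom; non-convergent fits
are dropped with a warning, and exact ties break deterministically (fewer
covariates, then name order). Prediction maps are confined to the
prediction polygon — the convex hull of visited cell centres from the
design-stable years intersected with the area of interest — with the 95%
confidence-interval width mapped as
`plogis(η + 1.96 se) − plogis(η − 1.96 se)`.

# Random forests

The explanatory forest grows 500 probability trees, each on a random 66%
subsample of cells drawn *without replacement* (the survey's description is
a random subset, not a bootstrap; out-of-bag bookkeeping works identically),
with 4 candidate predictors per split, correlated predictors retained.
Permutation importance is the mean out-of-bag accuracy drop when a
predictor is randomized (unscaled, so values are on the accuracy scale).

The predictive ensemble counters the heavy class imbalance by keeping all
presences and a seeded equal-size subsample of absences. Members differ in
`mtry` — multiples {0.5, 1, 2} of `floor(√p)`, deduplicated — and are
combined with non-negative weights summing to one, chosen to minimize the
squared error of stratified 10-fold cross-validated member predictions
against the 0/1 labels. The simplex-constrained least-squares problem is
solved exactly by active-set enumeration, which guarantees the ensemble's
CV error never exceeds any single member's. Temporal transferability is
measured leave-one-year-out: balance and fit on all other years, predict
every labelled cell of the held-out year (unbalanced), and report the AUC
(Mann–Whitney with ties counted one half).

# Strip-transect abundance

Density divides the birds seen within 300 m of the transect by the area
searched (distance × strip width: 0.3 km with one observer side in
2013–2014, 0.6 km with two sides from 2015), with no detectability
correction inside 300 m. Abundance multiplies density by the prediction
area (41,771 km² for the published polygon). The density variance is the
variance of per-day densities weighted by daily transect distance, centred
on the distance-weighted mean. The abundance variance multiplies the
density variance by the *area* — not the squared area — matching how the
published variances scale; the conventional delta-method alternative is
available via `propagate_squared = TRUE`, and the discrepancy is a caveat
worth knowing when comparing variances across studies of different areas.
Reported abundances round half-to-even to whole birds.

# The synthetic-survey generator

The generator's defaults describe the study conditions: the Channel/Celtic
Sea box, a 1-km grid, five October surveys along parallel north–south
transects at 10 kn with per-minute records, sea state as a clamped integer
autoregressive walk on 0–8, and a prevalence target of 2.2% of effort
cells. Environmental fields are white noise convolved with a Gaussian
kernel whose scale is set so the field's correlation function is
`exp(-d²/2L²)` with correlation length `L` (25 km by default; `Inf` gives
flat fields). Static fields (bathymetry, current speed) are shared across
years; dynamic fields get a fresh realization per year, and the true
suitability surface is re-evaluated on each year's fields with fixed slope
coefficients — interannual variation in the truth comes from the dynamic
environment, as it should. The logistic intercept is re-solved each year to
hold the configured prevalence: the mean of a logistic surface with strong
coefficients is dominated by the field extremes of the realization, so a
frozen intercept would let prevalence swing by an order of magnitude
between years; a year-varying baseline over a fixed habitat response is
also what a population with large interannual abundance variation looks
like.

Suitability is a logistic function of standardized covariates plus an
optional Gaussian bump centred on stratification index 1.9, so that truth
can peak at tidal fronts; the intercept is solved by root-finding so
expected prevalence matches the target. Sightings are Bernoulli draws per
cell-visit with probability suitability × detection probability, placed on
the track with a uniform perpendicular distance on [0, 1000] m; flocks are
optional via a zero-truncated geometric count. One random stream per
(seed, year, purpose) label keeps every generator independent, so adding a
new one never perturbs existing draws.

What the generator does *not* emulate: bird movement and flock spatial
structure, observer-side asymmetries, detectability trends with distance or
sea state, tide-resolved currents, and realistic fish fields. Passing
recovery tests therefore demonstrate that the estimators work when their
assumptions hold — not that those assumptions hold at sea.

## Design of the validation experiments

Three choices deserve explicit statement.

* **Recovery and transferability experiments use a strongly separable
  truth** (coefficients 2.5 and −2.0 on standardized stratification index
  and SST, prevalence 3%). These experiments verify that constrained AIC
  selection finds planted covariates and that the ensemble transfers across
  years when a strong, temporally stable signal exists; a weak-signal truth
  would confound estimator failure with honest statistical ambiguity (with
  ~70 presences, a mild covariate is legitimately droppable by AIC).
* **Fish "noise" fields in the importance experiment are white noise.**
  Spatially smooth random fields are spuriously correlated with any spatial
  presence pattern in samples of a few thousand cells, and permutation
  importance inherits that inflation — a well-known property of
  autocorrelated predictors, not a defect of the forest. White noise makes
  "signal outranks noise" a fair statement of what the machinery can do.
* **Problem sizes.** Validation surveys use a ~107 × 100 km sub-box of the
  study area with 8-km transect spacing and one to three survey years
  (roughly 1,200 labelled cells and 35 presences per year), and 20
  replicates per experiment; estimator calibration uses 200 simulated
  Poisson strip surveys. These sizes put every recovery question in a
  regime where the answer is unambiguous while keeping a full validation
  run in minutes.

# Numerical choices and degenerate inputs

Ties in AIC break by covariate count then name order; ties in AUC scores
count one half. Bilinear extraction is exact at nodes and refuses points
outside the node hull (missing with a warning). The stratification index is
missing on land (`h ≤ 0`) and where `u ≤ 0`; aspect is missing on flat
cells; single-day variance is zero with a warning; one-class held-out years
give a missing AUC with a warning; complete separation in a GAM flags the
fit rather than crashing the selection. The classification band around the
front value is closed (`|SI − 1.9| ≤ 0.1`), and the three classes partition
the line exactly even at floating-point boundaries.

# Known limitations

Observers are assumed to survey the whole 1-km cell when present, inherited
from the survey design; strip width and cell width differ, and no
distance-detection function is fitted. Aspect's circularity is ignored.
The abundance estimator has no availability-bias correction for birds on
the water, and no spatial abundance surface is attempted — the sighting
counts are too sparse to support one. The printed per-day effort splits of
the original surveys are not public, so published density *variances*
cannot be reproduced, only the density → abundance chain.
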