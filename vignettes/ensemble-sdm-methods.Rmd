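---
title: "Ensemble species distribution modelling for mangrove bivalves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble species distribution modelling for mangrove bivalves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mangrove bivalves of the genus *Anadara* live in the mud beneath red-mangrove
(*Rhizophora mangle*) forests. Mapping where they can live — now and under
future climate — is a hierarchical species distribution modelling (SDM)
problem: the habitat species must be modelled first, and its suitability
surface (the "ESRm" layer) then enters the bivalve models as a biotic
predictor alongside climate, soil, terrain, and distance-to-water layers.
`mangroveSDM` implements that full workflow as composable, tested stages:

1. climate downscaling by regression kriging (coarse ~1 km layers to the
   fine ~250 m analysis grid, with elevation as the regression covariate),
2. predictor preparation (depth-weighted soil aggregation per species,
   Euclidean distance to water, per-cell occurrence thinning),
3. surface-range-envelope (SRE) classification and three-criterion
   pseudo-absence sampling,
4. cross-validated member classifiers combined into a TSS-weighted mean
   ensemble, with KAPPA / TSS / AUC evaluation,
5. maxSSS-based binarization, four-category change maps, zonal area
   accounting, and centroid-based direction of shift.

Real inputs are read as single-band GeoTIFFs and occurrence CSVs. Because the
real geodata are large and access-restricted, the package ships a
synthetic-landscape generator whose ground truth (niches, habitat masks,
future displacement) is known exactly, so every downstream stage can be
tested for recovery rather than plausibility.

## Coordinate and raster conventions

All grids are planar, in metres, row 1 northmost, with a half-open pixel
model: cell `(r, c)` covers
`[x0 + (c-1)s, x0 + cs) x (y0 - rs, y0 - (r-1)s]` and its centre sits at
`(x0 + (c-0.5)s, y0 - (r-0.5)s)`. A projected metric plane (rather than
geographic degrees) makes area and bearing computations exact and testable;
synthetic landscapes carry no real CRS and real GeoTIFFs are used as-is.
The bundled GeoTIFF codec intentionally covers only what the pipeline
produces and consumes: single-band, uncompressed, square unrotated pixels,
ModelPixelScale/ModelTiepoint georeferencing, and the GDAL-style nodata tag.
Rotated model transforms are refused rather than silently mishandled.

## The synthetic landscape

Each environmental variable is a smoothed Gaussian noise field (dense
separable Gaussian smoothing, correlation length in cells) rescaled to a
target mean and spatial standard deviation, plus an optional linear trend
stated as a compass direction and a corner-to-corner amplitude. The default
roster emulates a humid tropical coast: annual mean temperature ~26 degC
rising toward the northeast (5 degC span), annual precipitation ~4000 mm
rising toward the southwest (2500 mm span), a wet-quarter temperature field
trending northwest-southeast, a dry-quarter precipitation field, and two
soil variables (bulk density, silt) generated as six standard depth-interval
layers (0-5 to 100-200 cm) with a gentle depth drift. Trend spans dominate
the within-field noise (roughly 10:1) because the recovery tests need the
niche geometry to be controlled by the gradients, not by individual noise
blobs; the noise magnitudes (a few tenths of a degree, a few hundred mm) are
what remains at 250 m once elevation is factored out.

Three constructions give the pipeline a recoverable ground truth:

* **Coarse layers are exact block means of the fine truth**, so the
  downscaler has a known target and its MAE/RMSE/R-squared are
  interpretable.
* **True suitability** is logistic-quadratic,
  `s(x) = plogis(b0 - sum_v w_v ((x_v - opt_v)/tol_v)^2)`, and presences are
  drawn without replacement with probability proportional to `s`. The
  habitat-cover mask is `s >= 0.5` dilated by one cell, giving the
  pseudo-absence exclusion a controlled overlap with the niche.
* **Future climate** is an additive delta per climate variable: a mean shift
  plus an optional planar gradient along a stated bearing. With temperature
  rising toward the northeast and warming applied uniformly, the isotherm
  band that satisfies the niche moves toward the southwest; precipitation
  deltas are sized so that both bands move the same fraction of the domain
  (e.g. +1.8 degC against a 5 degC span pairs with -900 mm against a
  2500 mm span). The demonstration niches put the current optimum slightly
  northeast of the domain centre so the displaced band stays inside the
  domain rather than being clipped at the edge — with the optimum centred,
  edge clipping distorts the centroid and the recovered bearing.

What the generator does **not** emulate: real coastline geometry, tides,
salinity, fishing pressure, GCM physics, or the spatial sampling biases of
archival occurrence records. Passing recovery tests therefore demonstrate
that the machinery is correct and unbiased under known conditions — not that
any particular real-world map is accurate.

## Downscaling by regression kriging

Each coarse climate layer is converted to points (one per cell centre),
split 70/30 into training and test sets, and modelled as an ordinary
least-squares trend on elevation plus ordinary kriging of the residuals.
Temperature-type variables (bio1-bio11) take the elevation regressor —
lapse-rate physics makes elevation a genuine linear predictor — while
precipitation-type variables (bio12-bio19) are kriged without it; the
assignment is overridable per variable.

The residual semivariogram uses 12 lag bins to half the domain diagonal and
is fit by weighted least squares (weights proportional to pair counts) for
an exponential family by default (spherical and Gaussian are available).
Numerical choices worth stating:

* the fitted range is capped at twice the maximum observed lag — beyond the
  observed lags it is not identifiable, and unbounded fits occasionally
  diverge on trend-like realizations;
* single-realization range estimates are heavy-tailed: with a generating
  range of 8 cells on a 30-cell domain, roughly 6-8 of 10 refits land
  within +/-50% of the truth regardless of weighting scheme, so the test
  suite asserts majority recovery rather than universal recovery;
* a flat residual variogram (zero sill, e.g. a noiseless linear trend)
  degenerates kriging to a neighbourhood mean of zero residuals, which is
  the correct limit;
* prediction uses the 32 nearest training points; the ordinary-kriging
  system carries the unit-sum constraint, so predictions at training
  locations are exact whenever the semivariance at distance zero is zero.

Validation reports MAE, RMSE, and R-squared (`1 - SS_res/SS_tot` about the
test mean) on the held-out 30%.

## Occurrences, envelopes, and pseudo-absences

Occurrence tables are cleaned by three rules — drop rows with missing
coordinates, drop exact coordinate duplicates, drop rows outside the study
extent — and later condensed to at most one presence per fine cell (the
first record by input order wins, for determinism).

The SRE envelope takes, per predictor, the `q` and `1-q` empirical quantiles
of the presence values (linear interpolation between order statistics, the
`stats::quantile` type-7 rule); `q = 0.025` keeps the central 95% per
variable. A cell is environmentally suitable iff every variable lies inside
its bounds. Pseudo-absences are then drawn uniformly without replacement,
exactly one per presence (1:1), from cells that are simultaneously inside
the study mask, outside the habitat-cover mask, SRE-unsuitable, and not
occupied by a presence. The habitat-cover exclusion applies to every
modelled species, including the habitat provider itself.

## Members, ensemble, and evaluation

The training table holds one row per occurrence or pseudo-absence with
predictor values read from the containing cell; rows on nodata are dropped
with a warning. The cross-validation design is `k = 3` stratified folds
repeated 10 times, and each algorithm is run 10 times (each run re-draws
the partitions under a run-specific seed), i.e. 300 member fits per
algorithm at the default design. Members are scored on their held-out fold:
sensitivity and specificity at the `p >= 0.5` rule, `TSS = sens + spec - 1`,
Cohen's KAPPA, and rank-based AUC with mid-ranks for ties.

The ensemble is the weighted mean of all members whose validation TSS
strictly exceeds 0.8, with weights proportional to TSS (summing to one).
Ensemble-level held-out scores pool, for every data row, the predictions of
exactly those members that held the row out, weight-average them with
renormalized weights, and score the pooled out-of-sample vector once.

Three member algorithms ship behind a registry interface (`random_forest`
via `randomForest`, `logistic` via `glm`, `decision_tree` via `rpart`);
further algorithms plug in via `register_algorithm()` without touching the
pipeline.

Variable importance permutes one predictor column at a time (three
permutations by default), recomputes ensemble predictions, and scores
`1 - cor(original, permuted)` clipped to `[0, 1]`, normalized across
variables to sum to 100. It is computed on the ensemble rather than per
member — the per-member-then-average variant differs only in weighting and
the ensemble-level view matches how the predictions are actually used.
Response curves sweep one predictor across its observed range with all
other predictors at their dataset medians; the reported suitability range
is the span of focal values whose curve reaches 0.5.

## Thresholding, change, and direction

maxSSS searches the candidate set (sorted unique probabilities plus 0 and 1)
exhaustively under the `p >= t` rule and breaks ties toward the smallest
maximizing candidate. Both thresholding policies are supported —
`fixed:0.5` (the rounded cut-off used for published-style maps) and
`maxsss` (species-specific) — with `fixed:0.5` the default.

Change maps follow the four-way algebra (negative = suitable now only,
positive = newly suitable, no-change = both, absence = neither; coded
0/1/2/3, nodata propagates). Areas are cell counts times `s^2/10^6` km2,
reported per zone plus a total row, with derived current
(= negative + no-change) and future (= no-change + positive) areas. The
direction of shift is the bearing (degrees clockwise from north, so 225 =
southwest) from the current to the future centroid of suitable cells,
unweighted by default — the simplest defensible statistic — with a
suitability-weighted variant available.

## The pipeline and its defaults

`run_pipeline()` orchestrates: landscape, downscaling, soil/DWB/thinning,
SRE and pseudo-absences, the habitat ensemble, ESRm injection, focal
ensembles, current projection, per period-by-scenario futures, and the
change/area/direction stage, all deterministic per the global seed. Future
focal-species projections use the scenario-matched future ESRm layer
(re-projected from the habitat ensemble under the future climate) because a
biotic predictor frozen at its current state would contradict the premise
that habitat itself responds to climate; `freeze_esrm: true` restores the
frozen behaviour. Scenario deltas are applied to the downscaled fine
layers directly — for mean shifts this commutes exactly with downscaling,
and it keeps a full demo run under ten seconds. Soil layers are held fixed
under future scenarios.

Defaults (all overridable in the YAML config): SRE `q = 0.025`; `k = 3`,
10 repetitions, 10 runs; ensemble cutoff 0.8 (strict); threshold
`fixed:0.5`; importance permutations 3. The demonstration configuration
uses a 48 x 48 fine grid (250 m cells, coarse factor 4), 100/130/94
presences for the habitat and two bivalve analogues, three scenario
intensities by two periods, and a deliberately small CV design (two
repetitions, one run, random forest only) so the demo and the test suite
stay fast; the benchmark and acceptance computations use the full
10 x 10 design.

## Known limitations

* The GeoTIFF codec does not read compressed, tiled, multi-band, or rotated
  rasters; reproject and flatten upstream.
* Kriging is plain regression kriging with a single covariate; no
  co-kriging or spatio-temporal variants.
* Pseudo-absence design implements exactly the three stated criteria; no
  minimum-distance buffering or environmental stratification.
* The centroid bearing is a whole-range summary; multimodal range changes
  (e.g. simultaneous poleward and coastal shifts) deserve inspection of the
  change map itself.
* Cross-validation is stratified by label only, not spatially blocked, so
  member scores on strongly autocorrelated data are optimistic in the way
  usual for this design.
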