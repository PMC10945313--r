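---
title: "Methods: ensemble distribution models, protected-area effectiveness and gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble distribution models, protected-area effectiveness and gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rangegap implements a desk-scale version of a workflow that is standard in
climate-change conservation assessment: ensemble species distribution
models (SDMs) for range-restricted taxa under present and future climate,
conversion of the model output into binary ranges and richness maps, a
randomization test of protected-area (PA) effectiveness, and a
representation (gap) analysis against area-scaled protection targets.
This vignette is the package's own account of each method, its
assumptions, the tunable parameters, and the numerical choices that make
runs bit-reproducible.

```{r setup, message = FALSE}
library(rangegap)
```

## The synthetic landscape

Real assessments of this kind consume bioclimatic raster stacks, curated
occurrence databases and PA polygon compilations. rangegap ships a
synthetic-data module so that every downstream stage can be exercised —
and validated against known truth — without any external download.

**Climate.** `generate_landscape()` builds each climate variable as white
Gaussian noise smoothed with an isotropic Gaussian kernel
(`autocorr_scale`, in cells; the kernel is truncated at three standard
deviations and convolution wraps around the grid edges, which keeps the
field stationary). Each layer is standardized to zero mean and unit
variance over valid cells, so climate values are in sd units throughout.
Future scenarios (`generate_future()`) add a per-variable mean shift plus
an optional autocorrelated anomaly field of standard deviation
`noise_sd`. The demonstration configuration uses a +1 sd shift for the
optimistic future and +2 sd for the pessimistic one, with `noise_sd =
0.3`: large enough that restricted-niche taxa lose substantial suitable
area, mirroring the strong range contractions such assessments report.

**Virtual species.** `generate_virtual_species()` follows the standard
virtual-species convention: an independent Gaussian response curve per
climate variable, multiplied across variables and rescaled so the best
cell scores 1. The *true range* is the set of cells at or above
`range_cut`, and the *endemism region* — the padded bounding box of the
true range — plays the role of the biogeographic calibration area that
restricts model fitting for endemic taxa. Occurrences are sampled without
replacement from the true range with probability proportional to
suitability. No survey-bias structure (roads, rivers, collector effort)
is modelled: passing recovery tests show the estimation machinery works
when detections follow suitability, not that it is robust to the biased
sampling of real occurrence databases.

**Protected areas and land cover.** `generate_protected_areas()` grows
contiguous blob footprints by seeded random accretion and labels each
with one of the three PA categories used throughout: strictly protected
areas (SPA), sustainable use areas (SUA) and indigenous territories (IT).
`generate_landcover()` thresholds a smoothed field so a chosen fraction
of cells is forest (two forest codes, two non-forest codes), spatially
clumped like a real land-cover projection.

All generators are pure functions of their seed and parameters; cells are
indexed `(row, col)` with row 1 at the top, and cell area is a scalar
configuration value (default 25 km², echoing ~5 km grid cells) — there is
no geodesic area computation on synthetic grids.

## Climate axes

Collinearity among bioclimatic variables is handled the usual way: a
principal component analysis on the standardized present-scenario values
over valid cells (`fit_axes()`), keeping the smallest number of axes
whose cumulative variance reaches `variance_target` (default 0.95). Two
choices matter for cross-scenario consistency:

* **Coefficient reuse.** The standardization constants and loadings come
  from the present scenario only and are reused for every future
  projection (`project_scores()`); futures are never re-standardized.
  This keeps the predictor space identical across time, so a uniform
  climate shift moves axis scores by a closed-form, loading-weighted
  amount.
* **Sign convention.** Each loading column is oriented so its
  largest-magnitude entry is positive, making results reproducible
  across linear-algebra backends.

The PCA is fitted on the whole valid grid rather than the union of
calibration areas; with standardized synthetic layers the two are
practically indistinguishable, and the whole-grid fit keeps the model
independent of the taxon set. Constant layers are dropped with a warning
before fitting. `write_axis_model()` serializes the constants to JSON so
projections re-run bit-identically.

## Ensemble distribution models

For each taxon, `build_training_set()` pairs the unique presence cells
with pseudo-absences drawn uniformly at random from the calibration
region excluding presence cells, at a 1:1 ratio by default
(`pa_ratio`). Uniform background at 1:1 is the most common default of
ensemble SDM toolkits; the ratio is configurable.

**Validation partitions** (`partition()`) follow the occurrence-count
rule used for endemic-bird assessments: taxa with 15 or more unique
occurrences get the geographically structured two-fold *checkerboard*
partition — cell `(r, c)` belongs to fold
`(floor((r-1)/b) + floor((c-1)/b)) mod 2` for block size `b` — while
taxa below 15 occurrences get random, label-stratified k-fold assignment
with `k = min(5, n)`. The default block size is a tenth of the
calibration-region width (minimum 2 cells, single-scale); if a
checkerboard fold ends up without presences the block is halved and, at
block size 1, the partition falls back to k-fold with a warning.

**Metrics.** Two evaluation metrics are computed per held-out fold: AUC
in its rank (Mann–Whitney) formulation — the probability that a random
presence outscores a random pseudo-absence, ties counting one half — and
the maximum Jaccard similarity `TP / (TP + FP + FN)` over all candidate
thresholds (the unique held-out scores).

**Estimators.** The algorithm registry is a pluggable contract (`id`,
`fit`, `predict`); two concrete estimators ship. `estimator_logistic()`
is a ridge-regularized logistic regression on linear plus quadratic axis
terms, representing the GLM/Maxent family. `estimator_gaussian()` scores
cells by `exp(-d²/2)` with `d` the Mahalanobis distance to the presence
centroid (shrunken covariance), representing the climate-envelope
family. Each estimator's raw map over the calibration region is min-max
rescaled to [0, 1] so differently scaled outputs average sensibly; for
future scenarios the present-fit scaling constants are reused and
predictions clamped to [0, 1], mirroring the axis model's
coefficient-reuse rule.

**Ensembling** (`ensemble()`) retains the algorithms whose mean metric is
at or above the mean of all algorithms' metrics and averages their maps
cell-wise. The at-or-above rule (rather than strictly above) guarantees a
non-empty retained set when algorithms tie. The ranking metric defaults
to the threshold-based Jaccard (the same family as the binarization
criterion) and can be switched to AUC.

## Binary ranges, masking and richness

`select_threshold()` scans every candidate threshold — the sorted unique
suitability values at the evaluation cells — and keeps the one maximizing
the Jaccard similarity between `suitability >= t` and the observed
presences, breaking ties toward the smallest threshold. The threshold is
selected once per taxon on present-scenario training records and reused
for that taxon's future binarizations, keeping present and future areas
comparable. All cell-wise comparisons use `>=` (attaining the threshold
counts as suitable), documented for bit-exact reproduction.

`apply_forest_mask()` intersects binary ranges with the forest land-cover
classes *after* binarization (the threshold is a climate quantity; the
mask is a habitat constraint), and the masked range is the one used for
all downstream area, richness and representation computations — including
the area that sets the protection target. Floodplain-restricted taxa can
have their future ranges limited to the present range
(`restrict_future_to_present()`, a cell-wise AND). `area_change()`
reports `100 × (future − present) / present`; a loss above 99% is flagged
as a complete loss of climatically suitable area. `stack_richness()` sums
binary ranges into a richness map.

## Protected-area effectiveness

`effectiveness_test()` implements the relocation null model: a PA's
observed mean richness is compared with the mean richness of 999 (by
default) random translations of its footprint within the study area.
Translation preserves size, shape and orientation — no rotation or
reflection — and a draw is accepted only when every translated cell lies
inside the study mask (rejection sampling, capped at 10,000 attempts;
areas that cannot be placed are flagged untestable rather than fatal).
Relocated footprints may overlap real PAs or each other: the null is a
pure placement null.

A PA is *effective* when its observed value strictly exceeds the null
value in at least 95% of randomizations
(`n_observed_greater >= ceiling(0.95 × n)` — 950 of 999); ties count
against effectiveness, the conservative reading. Alongside this counting
rule the add-one permutation p-value `(1 + #(null >= observed)) / (1 + n)`
is reported; it can never be zero, and the two can disagree only at the
boundary, so both are returned. Each PA's random stream is derived from
the master seed and its `pa_id`, making per-PA results reproducible and
independent of testing order. Under a richness field generated
independently of PA placement the effective fraction sits near the
nominal 5% (the test suite checks it stays within 1–10%, a band that
covers the discreteness of the counting rule and the spatial
autocorrelation of the field).

## Gap analysis

The representation target follows the classic area-scaled construction:
taxa with ranges at or below 1,000 km² should be 100% covered, taxa at or
above 250,000 km² need 10%, and between the anchors the target is
interpolated linearly in log10(area):

```
target(a) = 100 − 90 · (log10 a − 3) / (log10 250000 − 3)
```

The functional form between the printed anchors is the standard
log-linear interpolation; it is continuous, non-increasing and meets both
anchors exactly. Achieved representation is the percentage of range cells
inside the cell-level union of the scenario's PAs (overlapping PAs are
unioned, so double-counting is impossible), computed for three nested PA
scenarios: SPA, SPA+SUA, SPA+SUA+IT. Goal attainment is
`100 × achieved / target`, reported uncapped for transparency.

Categories follow the attainment boundaries: **Protected** at ≥ 90% of
the goal, **Partial gap** above 20% and below 90%, **Gap** above 0% and
up to 20%, **Not protected** at exactly 0% — or whenever the scenario
range is empty, so taxa lacking climate suitability in a future count as
unprotected regardless of nominal attainment. Because the PA scenarios
are nested, achieved representation is monotonically non-decreasing along
the nesting and a taxon's category can only improve.

## The pipeline, formats and problem sizes

`run_pipeline()` chains every stage from a single configuration list or
YAML file and writes all tabular outputs as CSV, grids as ESRI ASCII
rasters (a plain-text raster format; a JSON sidecar carries stack
metadata), PAs as GeoJSON cell-square polygons plus a lossless
rasterized-mask CSV, and a provenance file echoing the configuration and
every derived seed. Intermediates are files; no stage mutates another
stage's outputs, and reruns with the same seeds produce byte-identical
CSVs.

The bundled demonstration (`demo_config()`) uses a 50 × 50 grid, six
climate variables, 12 virtual taxa spanning 8–120 unique occurrences
(so both partition methods are exercised), 60 protected areas, 70%
forest cover and 999 randomizations — sizes chosen so a full run takes
seconds while every code path, including floodplain restriction and
complete range loss, is exercised. The test suite's calibration and
recovery checks use an 80 × 80 grid with 200 PAs and ten 50 × 50
virtual species respectively.

## Known limitations

* The two shipped estimators stand in for the larger algorithm sets of
  production SDM toolkits; the registry accepts user estimators, but no
  Maxent feature classes, random forests, SVMs or Gaussian-process
  models are re-implemented here.
* The synthetic landscape has no survey bias, no dispersal barriers or
  river-interfluve structure, and no geodesic geometry; conclusions
  about real Amazonian data cannot be read off the synthetic results.
* Richness effectiveness is unweighted (no rarity or area weighting),
  and PA management quality beyond the three category labels is out of
  scope, as are prioritization (site-selection) analyses.
* Wrap-around smoothing makes opposite grid edges correlated; at the
  default scales this is negligible relative to grid size, but very
  large `autocorr_scale` values on small grids will show it.
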