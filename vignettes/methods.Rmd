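---
title: "Methods: climate-stratified niche modelling of range change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-stratified niche modelling of range change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleorange)
```

## Scope and design

`paleorange` implements a complete climate-stratified niche-modelling
pipeline for reconstructing species range change across climatic time
slices, designed to run entirely on seeded synthetic data. Every stage —
climate generation, bioclimatic variables, environmental stratification,
the point-process suitability model, categorical ensemble synthesis, and
latitude-weighted area accounting — is an exported, unit-tested function;
`run_pipeline()` chains them behind a JSON run configuration whose defaults
encode the analysis constants of the motivating continental lion study
design: 125 strata, 18 zones, regularization multiplier 2, 100,000
background points, 10% omission allowance, and ensembles of nine
mid-Holocene and three glacial pseudo-GCM members.

## The synthetic world

`generate_climate()` realises a parametric climate whose structure carries
exactly the statistical features the downstream analysis assumes:

* **Temperature**: `base_temp − lat_lapse·|lat|` (defaults 28 °C,
  0.55 °C/deg), with a seasonal cosine whose half-amplitude grows linearly
  with |lat|/90 (default 18 °C at the pole) and flips phase across the
  equator. The twelve cosine samples sum exactly to zero, so the annual
  mean is the lapse profile to machine precision. `tmin`/`tmax` are
  `tmean ∓ diurnal_range/2` (default 10 °C) — a knob we added because the
  monthly-climate contract requires a temperature range but no stated
  parameter controls it.
* **Precipitation**: a dry background (15 mm/month) plus a Gaussian
  "pluvial belt" in latitude (peak 220 mm/month, SD 12°). Moving the belt
  between slices emulates pluvial/interpluvial phases: the default
  configuration shifts it north for the mid-Holocene and south (and
  stronger) for the glacial slice. A deterministic sinusoidal longitudinal
  modulation (`zonal_precip_mod = 0.3`) keeps the derived aridity fields
  two-dimensional; without it every bioclimatic field is a pure latitude
  band and the stratification degenerates to stripes.
* **Noise**: cellwise monthly Gaussian noise (default sd 1 °C / 1 mm); the
  same draw shifts `tmean`, `tmin`, `tmax` so their ordering is invariant.
* **Pseudo-GCMs**: each ensemble member adds an independent smooth random
  field (bilinear interpolation of coarse Gaussian noise, ~10-cell
  correlation scale; sd 2 °C / 25 mm) — mimicking the spatially coherent
  disagreement of coupled circulation models, not their physics.
* **Land masks**: a wavy coastal margin; the glacial mask is the present
  mask dilated by `sea_level_offset` cells (default 2), so glacial land is
  a superset of present land, as lowered sea levels imply.
* **Occurrences**: cells drawn multinomially proportional to a suitability
  surface, jittered uniformly within a disc of `jitter_km` (default 25 km;
  records are filtered at an inclusive 50 km error ceiling, the
  conventional cutoff for continental carnivore localities). The pipeline's
  generating intensity is log-linear in the standardised bioclimatic
  covariates with weights `(0.5, −0.5, 1.5, −0.5)`; recovery experiments
  use the sparser, stronger `(0, 0, 2.5, 0)`.

What the generator does **not** emulate: orographic and continental
climate structure, realistic coastlines, vegetation feedbacks (the "Green
Sahara" problem — circulation models famously under-produce mid-Holocene
Saharan greening, and our pseudo-GCMs inherit no such bias), sampling bias
in occurrence compilations, and temporally heterogeneous locality error. A
green test therefore establishes correctness of the *computations* under a
known generating law, not fidelity of any real-world reconstruction.

## Bioclimatic variables

Growing degree-days use a fixed 365-day calendar (`{31,28,31,…}`); monthly
mean below 0 °C contributes nothing. Temperature seasonality is the
*population* SD of the twelve monthly means × 100 (the bio4 convention;
the data source the field cites does not pin down the estimator, so we
document ours). PET uses Hargreaves —
`0.0023 · RA · (T̄ + 17.8) · √(Tmax − Tmin)` per day, clamped at zero —
with extraterrestrial radiation RA from standard solar geometry at
mid-month, matching the formulation behind the global aridity/PET
datasets; the function is pluggable should a Thornthwaite variant be
wanted. The aridity index is annual precipitation over annual PET, with a
configurable hyper-humid cap (default 100) where annual PET is zero — a
state reachable only in frozen synthetic worlds. PET seasonality is
CV × 100; the scaling constant is irrelevant downstream because the
stratification standardises every variable.

## Stratification

We standardise over land cells, take all four principal components (the
"99.9% of variation" consideration in the literature concerns variable
pre-selection, not component truncation), and run k-means with fixed k and
multiple seeded restarts. The published stratification lineage used
ISODATA-style clustering and a Weka random-forest classifier to transfer
strata onto each circulation model; we substitute k-means + nearest
centroid because both have exact small-instance oracles, and the training
labels are stored as the nearest-centroid assignment so that
`classify_grid()` on the training stack reproduces them bit-for-bit. Ties
break to the lowest stratum id everywhere. Zones are Ward clusters of
stratum centroids, renumbered by descending centroid growing degree-days:
zone 1 is the warmest, giving the "structured, interpretable" ordering the
zone concept exists for. Zone display names are configurable labels, not
reproductions of any published legend.

## The point-process model

MaxEnt's raw output is the intensity of an inhomogeneous Poisson point
process normalised over background; we fit that model directly. With
presence counts `c_i` (duplicates retained deliberately — the
no-deduplication convention), background cells as quadrature points of
weight 1 and features `f`, we maximise

```
ℓ(α, w) = Σ_pres c_i (α + f_i·w) − Σ_bg exp(α + f_j·w) − β Σ_j s_j |w_j|
```

with `s_j` the background SD of feature j and β = 2 by default. Internally
features are standardised by background mean/SD so the penalty is `β·|w|`,
and the L1 problem is solved *exactly* by L-BFGS-B on the split
`w = w⁺ − w⁻`, `w± ≥ 0` (the penalty is linear on the positive orthant);
the intercept is unpenalized. Feature classes default to linear +
quadratic; hinge features are excluded by design so that a brute-force
generic optimizer on the same objective can serve as an independent test
oracle. Non-convergence raises an error with the optimizer's diagnostic
rather than returning a silent partial fit. Under complete separation with
a weak penalty the penalized likelihood is genuinely unbounded; the
documented behaviour is that error, and the tests exercise the bounded
regime.

Predictions renormalise over each slice's own background (all land cells
of that slice by default), so per-slice maps are comparable as relative
occurrence rates; the present-day threshold is then applied to projected
paleo maps, as the study design prescribes.

**Threshold.** The modified lowest-presence threshold at allowance `e` is
the largest *observed* presence suitability `t` with
`mean(presence < t) ≤ e` (strictly-below counting; the source literature
names a "modified" variant without a formula, so this exhaustive-scan
definition is declared rather than inferred). Consequences worth noting:
`e = 0` returns the minimum presence value; ties at the bottom cannot be
partially omitted; the realized omission never exceeds `e`.

**Cross-validation.** Random k-fold splits presence cells into k seeded
folds (background shared); the spatial scheme builds four folds from a
two-scale checkerboard (`fold = 1 + fine_parity + 2·coarse_parity`, fine
blocks of `aggregation` cells, coarse of `2·aggregation`), partitioning
presences *and* background so train and test are spatially disjoint. AUC
is the rank probability that a held-out presence outranks a test
background cell (ties count ½). Two behaviours deserve emphasis because
they are properties of the evaluation, not bugs: (i) when presence cells
are inside the test background, perfect separation still yields
AUC `= 1 − n_pres/(2·n_bg)`, not 1; (ii) spatial CV only falls below
random CV when the blocks are larger than the environment's
autocorrelation scale — with small blocks the folds are environmentally
interchangeable and the two schemes coincide. Our acceptance comparison
therefore uses aggregation 10 on the 2° grid (20°/40° blocks), a
continental spatial-independence scale.

## Categories, ensembles, areas

The five-class favourability scheme is left-closed/right-open with the top
interval closed: `[0,10)` unsuitable, `[10,40)` low use, `[40,60)`
utilised, `[60,80)` favoured, `[80,100]` highly favoured. The printed
scheme's "<10%" upper bound forces the 10% boundary into "low use"; all
other boundaries follow the same closure. Ensemble combination is cellwise
(each pseudo-GCM member carries its own strata classification): strict
mode, a two-way tie between *adjacent* classes becomes the joint class,
any other tie is "uncertain" — the published rule is given by example, so
"no agreement" is operationalised as exactly that. For area accounting the
fixed collapse table maps "highly favoured/favoured"→highly favoured,
"favoured/utilised"→favoured, "low use/utilised"→utilised, and
"unsuitable/utilised"→low use. That last pair is asymmetric as printed; we
implement the table verbatim behind a single replaceable mapping rather
than second-guessing a transposition. The one joint class the combiner can
produce that the table omits ("unsuitable/low use") passes through
unchanged, keeping `collapse_classes()` idempotent and total on valid
inputs.

Cell areas use the exact spherical band formula on the authalic-radius
sphere (R = 6371.0072 km); category areas partition slice land area at
machine precision, and percentages are reported against land area within
the modelling extent (not the full raster rectangle) — the study's figures
do not disambiguate this, so we document the choice. Change tables flag
slices whose total land areas differ, the signature of sea-level mask
changes.

## Numerical conventions

* Every generator and fit is a pure function of (parameters, seed); seeds
  are localised so no function disturbs the caller's RNG stream, and stage
  seeds are derived arithmetically from the one config seed.
* Tie-breaks: nearest-centroid and k-means label ties to the lowest index;
  thresholds scan observed values only.
* Degenerate inputs error early with informative messages: empty masks,
  all-zero suitability, unfitted models, misaligned grids, omission
  allowance outside `[0,1)`.
* Raster interchange is a headered ASCII grid, round-trip exact at 17
  significant digits; models serialise to JSON. (The environment provides
  no GDAL-backed R raster stack, so GeoTIFF I/O is out of scope; the ASCII
  fallback is the documented interchange format.)
* The run configuration is JSON (no YAML parser is available in the
  supported dependency set).

## Known limitations

* The climate generator is a caricature: it validates algorithms, not
  climatology. Nothing here should be projected onto real species.
* k-means with restarts is a local optimiser; stratum identity is stable
  per seed but not canonical across seeds (zone *ordering* is, via
  warmth).
* The PPM excludes hinge/threshold features and any clamping of projected
  covariates; extrapolation beyond the training covariate range is
  unflagged.
* Occurrence positional error is modelled as uniform disc jitter at a
  single radius; real locality compilations mix error scales and
  sampling biases that the AUC comparisons here cannot expose.
* Table-1-style locality counts are a parameter (`n_occurrences`); the
  compiled total printed in the motivating study is internally
  inconsistent (rows sum to 1,106, total printed 1,135), so no particular
  value is privileged.
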