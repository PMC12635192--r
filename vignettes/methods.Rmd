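---
title: "Climate niche models for forest pests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate niche models for forest pests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestniche)
```

# The problem

Forest insects and pathogens track climate. Given presence-only occurrence
records of a pest species and gridded climate, we want to (i) delimit the
region of climate space the species occupies — its climate niche — (ii)
project that niche onto geographic space under current and future climates,
and (iii) translate the projections into quantities a forest manager can
use: host wood volume inside the suitable region, and maps of how many pest
species find a cell climatically suitable.

`pestniche` implements this pipeline over six bioclimatic variables: mean
annual temperature (MAT), mean daily minimum of the coldest month (MINTCM),
mean daily maximum of the hottest month (MAXTHM), all °C; and annual,
coldest-quarter and hottest-quarter precipitation (PREC, PRECCP, PRECHP),
all mm. These six summarize both average and extreme conditions, which is
what range-limiting physiology tends to respond to.

# Occurrence screening

Raw aggregated occurrence data (GBIF-style) are noisy. The screen is
order-fixed and fully audited:

1. **Metadata filters.** A record survives iff it has coordinates, carries
   no geospatial-issue flag, has a year strictly greater than 1950, and is
   not based on a fossil specimen. The year cutoff is a strict inequality:
   a 1950 record is removed. A record failing several clauses is counted
   against the first failing clause in the order above; the attribution
   rule affects only the per-clause bookkeeping, never the totals. Fossils
   are recognized by `basisOfRecord == "FOSSIL_SPECIMEN"`
   (case-insensitive), the standard vocabulary term.
2. **Landmass restriction.** Records whose containing cell is nodata in the
   land mask are dropped.
3. **10-km thinning.** Intensive local surveys produce clusters of
   quasi-duplicates that would otherwise dominate a fit. Records are
   indexed on a fixed global 10 km × 10 km grid and one record is kept per
   occupied cell. The grid is defined in a world cylindrical equal-area
   projection on the authalic sphere with origin (0, 0): equal-area keeps
   "10 km" meaningful at every latitude, and the fixed origin makes results
   reproducible. Within a cell the record with the lexicographically
   smallest (year, lon, lat) is retained — a deterministic rule chosen so
   that thinning is invariant to the order of the input file (an input-row
   tie-break would not be); input position breaks ties only between
   byte-identical duplicates, where the choice is unobservable.
4. **Minimum-record gate.** Species with fewer than 30 surviving records
   are reported but not modelled (inclusive: exactly 30 passes).

Each stage is idempotent, and `filter_report` reconciles
input − removals = output exactly at every stage.

# The rectilinear envelope model

The classic Bioclim/ANUCLIM summary: per variable, the min, 5th percentile,
mean, median, 95th percentile and max of climate at the occurrence points
(quantiles by linear interpolation, R type 7). Classification of a cell is
rectilinear — the suitable region in climate space is a Cartesian product of
intervals:

* **unsuitable** if any variable falls outside `[min, max]`;
* **core** if every variable lies within `[p05, p95]`;
* **marginal** otherwise.

The 5/95 pair is the conventional Bioclim core envelope; the percentile
pair is a parameter (`core_percentiles`) since the convention is not
universal. Both the class raster and a continuous score raster are emitted,
so users can present either the binary envelope or a graded surface.

The score is a Nix-style percentile distance:
`score = min_v min(p_v, 100 − p_v) / 50`, where `p_v` is the empirical
percentile of the cell's value among the training values of variable `v`.
Percentiles use Hazen plotting positions `(i − 0.5)/n` with linear
interpolation, clamped to 0/100 outside the training range. Hazen positions
were chosen deliberately: they place every in-range value — including the
training extremes themselves — strictly inside (0, 100), so the score is
positive exactly on the suitable region and zero exactly on the unsuitable
one, and the sample median maps to percentile 50 (hence score 1) for both
odd and even n. Envelopes fitted on supersets of points can only widen.

# The maximum-entropy model

The second model is a from-scratch presence-background maximum-entropy
(MaxEnt-type) estimator. Let `f(x)` be a vector of features of the climate
`x`, and let `B` be a background sample of the available environment. The
model is the Gibbs distribution over the background

$$p_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)}, \qquad
Z(\lambda) = \sum_{x \in B} e^{\lambda \cdot f(x)},$$

whose weights minimize the convex objective

$$F(\lambda) = -\frac{1}{n}\sum_{i=1}^{n} \lambda \cdot f(x_i)
  + \log Z(\lambda) + \sum_j \beta_j |\lambda_j|.$$

This is the distribution of maximum entropy subject to (soft) constraints
that the model's expected features match the presence means; the L1 term
relaxes each constraint by `β_j`, which controls smoothness.

**Features.** Linear, quadratic and pairwise-product transforms of the six
variables, plus forward hinges `max(0, x − k)`, reverse hinges
`max(0, k − x)` and step (threshold) indicators `1(x > k)`, with 32 knots
per variable placed at equally spaced background quantiles. A fixed knot
grid at quantiles covers the observed range with bounded feature counts
(603 with all classes); knotting at every distinct data value would grow
quadratically with data size for no benefit at these scales. All features
are min–max standardized to [0, 1] on the background, and features constant
on the background are dropped. Feature classes default by presence count
(linear below 10; + quadratic below 15; + hinge below 80; everything from
80), overridable; categorical features are omitted because all six
predictors are continuous.

**Regularization.** `β_j = reg_multiplier × max(σ̂_j, 10⁻⁴)/√n`, with
`σ̂_j` the presence-sample standard deviation of the standardized feature —
a simplified version of the published MaxEnt defaults, keeping the
essential scaling (looser penalties for more variable features, tighter
with more data). The multiplier defaults to 1.

**Solver.** Monotone FISTA: accelerated proximal gradient with
soft-thresholding, backtracking line search, and the safeguard of never
accepting an iterate that increases the objective — so the stored objective
trace is non-increasing by construction, which the tests assert.
Convergence requires both an objective improvement below `tol` and the KKT
stationarity conditions within `10 × tol` (for inactive weights the smooth
gradient must lie within `[−β_j, β_j]`; for active ones the subgradient
must vanish). Against an independent box-constrained quasi-Newton oracle on
the smooth split form `λ = a − b, a, b ≥ 0`, the converged objective agrees
to 10⁻⁵, and with linear features and vanishing penalty the fitted
background expectations reproduce the presence feature means to 10⁻⁴ — the
defining moment-matching property. The function default is `tol = 1e-6`;
the pipeline uses `1e-4` for its routine per-species fits, where the
remaining weight movement is far below any quantity reported downstream.

**Background.** 10,000 locations drawn uniformly over valid land cells
(without replacement while the land can supply them, with replacement
otherwise), placed at cell centres. A global uniform background is the
package default, matching a workflow that models many species of widely
varying extent with one consistent recipe.

**Outputs.** `raw` is the Gibbs probability (sums to 1 over the training
background — asserted to 10⁻⁸); `cumulative` is the percent of background
raw mass at cells scoring no higher; `logistic` is the entropy-calibrated
transform `e^H r/(1 + e^H r)` with `H` the entropy of the fitted background
distribution, which maps a typical cell of a near-uniform model to ≈ 0.5.
Logistic is the package's display default; the choice of display scale is
an assumption, and all three are available. When projecting onto new
climates, predictors are clamped to the training range so features are
never extrapolated.

**Evaluation.** Training AUC (rank-based, ties at ½) and permutation
importance: each variable's column is permuted jointly across presence and
background rows, the mean AUC drop over `n_permutations` shuffles is
floored at zero, and drops are normalized to sum to 100 (uniform shares if
no variable matters). No held-out split is made at this stage;
cross-validation machinery is out of scope.

# Future climate: the delta method

Future stacks are built by perturbing the high-resolution baseline with
coarse GCM anomalies: additive for the three temperature variables
(`future = baseline + Δ`), multiplicative for the three precipitation
variables (`future = baseline × ratio`) — the standard delta convention,
which preserves fine-scale structure and keeps precipitation nonnegative.
Ratios must be strictly positive and are capped to [0.1, 10] at ingest
(with a message) because near-dry cells in GCM output can produce wild
ratios. Multi-GCM composites average temperature anomalies arithmetically
and precipitation ratios in log space (geometric mean), so halving and
doubling are symmetric around 1. Scenario bookkeeping covers the three SSPs
(SSP1-2.6, SSP2-4.5, SSP5-8.5) and three periods (2011–2040, 2041–2070,
2071–2100). Anomaly grids must be supplied already aligned to the baseline;
interpolation of coarse GCM fields is the caller's responsibility, and no
stage of the package ever resamples implicitly (misalignment is an error).

# Risk and richness

`volume_at_risk` sums host wood volume (m³) over cells that are suitable
under a binary mask, optionally inside a region mask, and reports suitable
area with host present in cells and km² (cosine-latitude cell areas on
geographic grids; face-value cell sizes on projected ones). The default
mask for risk accounting is the full envelope (class ≠ unsuitable) — the
conservative, inclusive choice; a maxent-based rule (logistic ≥ the 10th
percentile of presence predictions) is selectable. Volume is additive over
disjoint regions and monotone in the mask, both asserted.

`stack_richness` counts, per cell, the species whose suitable region covers
it; `richness_change` subtracts two such maps and `area_with_change`
reports the area at or above a chosen gain (the headline convention is a
gain of ≥ 5 species). A nodata cell in one species' mask counts as 0; the
output is nodata only where every input is.

# The synthetic study system

All tests run on generated worlds, so the whole pipeline is exercised with
known ground truth and no downloads:

* **Climate.** MAT is a smooth north–south gradient (25 °C span by default,
  roughly boreal-to-subtropical) plus autocorrelated noise; MINTCM and
  MAXTHM are MAT minus/plus strictly positive seasonal offset fields; PREC
  is lognormal around 800 mm; PRECCP and PRECHP are smooth fractions of
  PREC whose sum stays below it; a smooth field thresholded at the land
  fraction (default 0.7) defines the coastline. Spatial autocorrelation
  comes from a separable moving-average of white noise (default kernel
  width 7 cells) — the simplest fully reproducible smoother, with no
  geostatistical machinery. Default worlds are 100 × 100 cells of 0.25°.
* **Species.** A true niche is a Gaussian bell in the six-variable space;
  records are drawn by rejection over land cells with acceptance
  probability `rate × exp(−½ Σ((x − centre)/spread)²)`, then jittered
  uniformly within the cell, with years uniform on 1960–2020. Because the
  true suitability surface is analytic, model skill is measured as rank
  correlation against it. Test species constrain mainly MAT (spread
  2.5 °C) and leave the other variables effectively free (spread = 3 SD of
  the landscape), so permutation importance has a known right answer.
  The attainable AUC is bounded by the overlap between a 2.5 °C niche and
  a 25 °C landscape gradient; the recovery thresholds (AUC ≥ 0.85,
  Spearman ≥ 0.8 at n = 200) are package acceptance settings under these
  conditions, not claims about real data.
* **Dirty records.** Violators of each metadata clause are appended with a
  hidden provenance column, which the CSV reader strips; tests can
  therefore assert exact per-clause removal counts without trusting the
  filter under test.
* **GCM anomalies.** Temperature anomalies are `warming × (1 + 0.1 field)`
  and precipitation ratios `ratio^(1 + 0.1 field)` with a smooth
  standardized field, so the zero-warming/unit-ratio delta is exactly the
  identity and the spatial mean tracks the nominal change. The random
  stream is salted with the GCM id.
* **Hosts.** Wood volume is distributed over land proportionally to a host
  niche's suitability times lognormal abundance noise and normalized to a
  prescribed total, so conservation checks are exact. In the demonstration
  run, host trees are given broader, poleward-shifted niches relative to
  their pests, reflecting the real situation in which host range exceeds
  the pest's current climate envelope and warming can open new host area.

What the generator does **not** emulate: dispersal limitation, biotic
interactions, sampling bias correlated with accessibility, taxonomic
error, coordinate-precision artefacts, or realistic coastline and
topography. Passing recovery tests therefore demonstrates correctness of
the estimators under their own assumptions, not fitness of any particular
real-world model.

# Numerical and format choices

* Rasters are single-band uncompressed float32 GeoTIFFs with
  ModelPixelScale/ModelTiepoint georeferencing, a CRS citation, and a
  GDAL-style nodata tag; a write/read round trip is exact at float32
  precision. Cell-centre coordinates, row 1 at the northern edge; a point
  on a cell boundary belongs to the cell to its south-east. Sampling is
  nearest-cell with no interpolation. Multi-band, compressed or
  ungeoreferenced files are rejected with distinct errors rather than
  guessed at.
* All multi-grid operations require exactly aligned geometries. The
  resolution-matching that produced any particular real dataset is outside
  the package; callers align first.
* Every random stage takes an explicit seed; child streams (per GCM, per
  species, per host) are derived from the seed plus a text salt, keeping
  whole runs reproducible from one integer. Rerunning the demonstration
  with the same seed reproduces byte-identical artifacts, which the
  acceptance tests verify by checksum.
* The run log (which contains timings) is excluded from the manifest's
  checksums; everything else a run writes is listed with its MD5.

# Problem sizes

The test suite and the acceptance script run on 100 × 100 worlds with
10,000 background points for the recovery and end-to-end checks, and
20–40-cell worlds for oracle comparisons, which keeps a full run in the
tens of seconds on one CPU while leaving every code path exercised at its
default settings (10-km thinning, 30-record gate, regularization
multiplier 1, 10,000 background points).

# Known limitations

* Training-data AUC only; no cross-validation or bootstrap replication.
* No bias grids or target-group background; the background is uniform over
  land.
* Unweighted masked volume sums: a suitability-weighted accounting (for
  example discounting "low-quality" marginal habitat) is not defined here,
  though the class and score rasters give callers what they would need.
* No reprojection, mosaicking or resampling; no categorical predictors.
* The occurrence reader handles the package's Darwin-Core-inspired CSV
  dialect, not arbitrary archives; taxonomic reconciliation is out of
  scope.
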