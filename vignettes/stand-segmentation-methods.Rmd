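---
title: "Forest stand delineation and area-based inventory from airborne LiDAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest stand delineation and area-based inventory from airborne LiDAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`standseg` implements a complete area-based forest inventory chain for
airborne LiDAR: rasterization of the point cloud into segmentation bands,
automatic delineation of forest stands by seeded region growing with
threshold merging, plot-level sparse Bayesian regression of stand
parameters, and aggregation of 20 m cell predictions to stand level. A
seeded synthetic-scene generator provides ground truth for every stage, so
the whole chain is testable without any external data.

## The segmentation bands

Stands are delineated on a three-band composite at 4 m resolution
("DHH"): vegetation **density**, canopy **height**, and a land-cover
**classification**.

* The height band is the per-pixel 85th percentile (nearest rank) of the
  height-normalized return heights. A high percentile is used instead of
  the maximum so single outlier returns cannot dominate a pixel; at
  typical return densities it still tracks dominant tree height closely.
* The density band is the fraction of a pixel's returns above a
  vegetation break, by default a fixed 1 m height. The alternative
  reading — counting returns above the pixel's own percentile height —
  is available as `mode = "percentile"` in `density_raster()`; we default
  to the fixed break because the regression feature list uses 1 m breaks
  throughout and the fixed rule is deterministic per pixel.
* The classification band is a maximum-likelihood land-cover map (bare
  land, low vegetation, forest) assuming per-class per-band normal
  densities with equal priors; ties go to the lowest class index. Its
  quality is summarized by Cohen's kappa against reference labels.

Height normalization subtracts a bilinearly interpolated DEM built from
per-cell minima of ground-classed returns, with empty cells filled by
iterative 8-neighbour averaging. Heights in (-0.5, 0) m are clamped to 0;
larger negative values indicate a DEM mismatch and raise an error.

Before compositing, the height and density bands are smoothed: two 5 x 5
median passes followed by an edge-preserving mean-shift filter (spatial
radius 3 px; spectral radius 2 m for height and 0.5 for density; at most
100 iterations, tolerance 1e-4). The median passes remove isolated noise
pixels and most canopy-gap texture; the mean-shift averages within
plateaus while leaving steps larger than the spectral radius untouched,
which is exactly the property stand boundaries need. Stand delineation
targets management units, not individual crowns or gaps, so fairly heavy
smoothing is appropriate; the window sizes are package defaults, not
tuned per scene.

The composite stores min-max normalization for the density and height
bands (segmentation operates on a common [0, 1] scale) alongside the raw
bands (merging thresholds are expressed in raw band units — density
ratio, metres — because their published magnitudes only make sense
there). The categorical class band has no meaningful arithmetic; its
"difference" is defined as 0 for equal labels and 1 otherwise, a region's
class "mean" is its modal-class fraction, and its "sd" slot carries the
impurity (1 - modal fraction).

## The delineation algorithm

Segmentation proceeds in two stages, each governed by a published
parameter group (seven groups ship with the package, as R constructors
via `parameter_group()` and as YAML fixtures under
`inst/extdata/params/`).

**Gradient and seeds.** A band-weighted central-difference gradient
magnitude (one-sided at edges, 0/1 differences on the class band) is
rescaled to [0, 1] by its maximum. Seed points are unassigned pixels that
are 3 x 3 local minima of this gradient with value at or below the
current priority level; of each 4-connected equal-valued plateau only the
row-major-first pixel seeds, so seeding is deterministic.

**Limited iterative region growing.** The priority function is an
ascending schedule of seed-admission levels (e.g.
0/0.1/0.2/0.3/0.5/0.7/1.0). At each level, new seeds are searched on the
still-unassigned area, the labels are reset, and best-first growing
restarts from the combined seed set: the frontier pixel with the smallest
dissimilarity to an adjacent region is annexed, where dissimilarity is
the band-weighted L1 distance between the pixel and the region's running
mean (modal-class fraction for the class band). A pixel is admitted only
if its dissimilarity is at most `competition_threshold * i`, with `i` the
1-based level index; `growth_scaling = FALSE` switches to the constant
bound reading in which the levels act purely as the seed schedule. Ties
resolve by smaller dissimilarity, then smaller segment id, then row-major
pixel order, making the partition fully deterministic. After the last
level the remaining pixels attach to their most similar adjacent region
without a bound. The exact semantics of the original software's
"priority function" and "competition threshold" are proprietary; both
interpretations here are documented switches, not claims about it.

**Merging.** Four rounds of per-band mean/sd difference thresholds are
applied in escalating order, and the final round is then repeated until
no admissible pair remains ("at least four" merge passes). In one sweep,
each segment (ascending id) merges with its most similar *admissible*
neighbour — the neighbour minimizing the weighted sum of
|mean difference| + |sd difference| among those passing every band
threshold and the 50 000 m^2 area cap — and symmetrically with any
neighbour whose own most similar admissible partner it is. We select
among admissible neighbours rather than testing only the single nearest
neighbour because the latter deadlocks as soon as every segment's nearest
neighbour fails one band while other admissible neighbours exist;
consolidation then stops far short of stand scale. Statistics are
recalculated immediately after every accepted merge. Finally, segments
below the 500 m^2 minimum mapping unit are absorbed into their most
similar neighbour, smallest first, with thresholds (and the area cap)
waived. Labels are then compacted and polygonized along pixel edges
(4-connectivity; 8-connectivity would create corner-touching stands with
ambiguous topology).

Because the area cap is far below a 512 m scene divided into five
stands, correct behaviour necessarily over-segments large stands; the
package's comparison report (`compare_segmentations()`) therefore
emphasizes the adjusted Rand index and boundary precision/recall rather
than raw counts.

One published table ambiguity is resolved as follows: the parameter table
prints only three priority-function strings and two competition
thresholds across seven columns (the text confirms only two distinct
settings exist). We assign groups 1-4 the 0.02 threshold with levels
0/0.1/0.15/0.2/0.3/0.5/1 and groups 5-7 the 0.04 threshold with levels
0/0.1/0.2/0.3/0.5/0.7/1.

## Stand parameters and the regression

Field plots are 20 m squares (400 m^2). From each plot's tree list the
package computes Lorey's mean height `H = sum(h_i g_i) / sum(g_i)` (m),
the quadratic mean DBH `D = sqrt(sum(d_i^2)/N)` (cm), the basal area
`G = sum(pi (d_i/200)^2)` (m^2 — the diameters are recorded in cm, so the
conversion to metres is required for the stated unit; the literal-cm
variant is available for audit), and the stand volume
`V = sum(c0 d_i^a h_i^b) / 400 * 10000` (m^3/ha) with the fixed
coefficients c0 = 0.000053108582, a = 1.778667, b = 1.1280516. Empty
plots report zeros with an explicit `empty` flag rather than NaN so
downstream tables stay numeric. Basal area is emitted both per plot and
per hectare, clearly labelled, since published tables are ambiguous on
this point.

Each plot's LiDAR predictors (53 named features, versioned in
`feature_manifest()`) cover height percentiles p5-p95 for first- and
last-pulse returns (single returns count as both), the mean first-pulse
height above 5 m, the first-pulse height sd, below-1 m return ratios,
intensity mean/sd/quartiles per pulse class, and canopy cover (fraction
of first-pulse returns above 5 m). The original software's exact
76-variable list is unpublished; this manifest covers every named
category and is what the models and predictions share.

The estimation engine is sparse Bayesian linear regression
(relevance-vector style) *over features*, not a kernel over samples: the
model must select an optimal subset of LiDAR variables, which is the
feature-selection reading of sparse Bayesian learning. Weights carry
independent zero-mean Gaussian priors with per-weight precisions
estimated by type-II maximum likelihood: `Sigma = (sigma^-2 Phi'Phi +
A)^-1`, `mu = sigma^-2 Sigma Phi' y`, `gamma_i = 1 - alpha_i Sigma_ii`,
`alpha_i <- gamma_i / mu_i^2`, `sigma^2 <- ||y - Phi mu||^2 / (n - sum
gamma)`. Features and response are standardized internally, so the
pruning ceiling (default 1e4) is scale-free and removes weights below
roughly 1% of the response sd; the intercept is never pruned, pruned
features never re-enter, and exact duplicate columns are deduplicated up
front because the symmetric split of weight across perfect copies is a
stable non-sparse fixed point. The linear systems are solved through a
Cholesky factorization with escalating diagonal jitter (from 1e-10 of the
mean diagonal) when needed. The fixed-point precision updates are not a
strict ascent method: the log marginal likelihood can dip by a fraction
of a nat early in a fit before climbing; the tests assert the overall
climb and bound the cumulative dips instead of strict monotonicity.
Model verification uses leave-one-out: n refits, each predicting its
held-out plot, scored by RMSE%, Bias% and squared Pearson correlation
(with the adjusted variant and the exact t-transform p-value).

For inventory, the labelled scene is tessellated into 20 m cells (the
field-plot size, so cell features live on the same scale the models were
trained on); each cell belongs to the stand owning the majority of its
pixels, whole cells are never split, and cells without returns are
flagged rather than predicted. Stand records are cell-area-weighted means
of H, D and the per-area densities G and V; with equal cells this is a
plain mean, and no published aggregation rule exists to follow more
closely.

## The synthetic scene

The generator emulates the structure the analysis assumes, with one
global seed fanned out to per-stage seeds by a stable hash of the stage
name:

* **Stand mosaic** — seeded Voronoi of random pixel centres (ties to the
  smaller index), post-processed so every label is one 4-connected
  region. Plot selection uses random non-overlapping placement with
  bounded retries, as no published spatial selection rule exists.
* **Regimes** — defaults emulate dense, internally homogeneous
  mountain-spruce plantations with strong between-stand contrast: one
  low-vegetation stand and four forest stands at 3000/2200/1500/1000
  stems/ha, DBH 10/16/24/32 cm, heights `h = a d^0.7 + eps` reaching
  about 6/12/18/24 m, narrow conifer crowns (radius 0.08 m per cm DBH).
  Narrow crowns and high stem densities give a smooth canopy-cover field
  at 4 m resolution, matching the within-stand homogeneity that stand
  delineation presupposes; open woodland with large isolated crowns
  produces gap texture this algorithm is not designed to regard as
  boundaries. DBH is truncated normal (> 2 cm), heights truncated above
  1.3 m (breast height).
* **Point cloud** — pulses on a jittered grid at 3 pulses/m^2 over a
  gently sloping bilinear terrain (so height normalization is genuinely
  exercised). Crowns are solid paraboloids with apex at the tree top and
  base at half the height; a pulse under one or more crowns returns a
  first return from the highest crown surface plus, with probability
  0.35, a last return from the ground; other pulses give a single ground
  return. Gaussian ranging noise has sd 0.1 m; intensity is drawn per
  return class (ground 20 +/- 5, vegetation 40 +/- 8). No waveform or
  radiative-transfer simulation is attempted.
* **Aerial image** — three bands with per-class Gaussian radiometry on
  the raster geometry.
* **Plot truths** — the stand-parameter formulas applied to each plot's
  exact tree list.

What the generator does *not* emulate bounds what passing tests show
about real data: tree positions are uniform (no clustering or
inhibition), one allometry per stand, no species mixtures within stands,
no occlusion or scan-angle effects, and class radiometry is exactly
normal. Tests passing here demonstrate the chain is implemented
correctly and recovers known structure, not that the printed accuracy
figures of any particular survey would be reproduced.

## Numerical conventions and problem sizes

Percentiles are nearest-rank on sorted values (integer-hit semantics;
interpolation would depend on the return count). Pixel coordinates are
0-based row/col with row 0 at map north, the origin at the outer NW
corner, and half-open pixel intervals — a point on a shared edge belongs
to the pixel with the larger row/col. Nodata is a -9999 sentinel, masked
in all statistics. Areas are pixel counts times 16 m^2 at 4 m pixels, and
the published 50 000 / 500 thresholds are read in m^2 (the study system
is metric). All tie-breaks (seed plateaus, competing regions, merge
partners, modal classes) resolve to the smallest index, so every stage is
bit-reproducible.

The test-suite simulations use a 512 m x 512 m scene (128 x 128 pixels,
roughly 800 000 returns, 94 plots split 60 training / 34 validation) for
the end-to-end checks, 256 m scenes for the ten-seed merging-monotonicity
sweep, and 16 x 16 or smaller grids wherever a brute-force oracle is
compared exactly; these sizes exercise every code path at full fidelity
while keeping the suite quick to run.
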