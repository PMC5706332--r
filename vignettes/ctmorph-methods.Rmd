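---
title: "Quantifying plant tissue microstructure from micro-CT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plant tissue microstructure from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctmorph)
```

## The problem

X-ray micro-CT resolves the 3D anatomy of fleshy plant tissues — apple
and pear hypanthium, tomato mesocarp — at 2.5–3 µm voxels, but contrast
between adjacent, water-filled cells is essentially nil. Conventional
segmentation therefore leans entirely on the dark intercellular
airspace, and its power falls with porosity: apple flesh (~20% air)
segments acceptably, pear (~10%) and tomato (~5%) yield angular,
implausibly large cell aggregates. Impregnating the tissue with a heavy
cesium-salt solution brightens the intercellular interfaces (a
boundary effectively ~2 voxels wide at this resolution) and floods a
majority of the airspaces, so that cell boundaries become directly
detectable. ctmorph implements the full quantitative workflow around
such scans: intensity classification with Sobel edge assistance, 3D
watershed separation, border-object removal, equivalent-diameter and
sphericity debris filtering, edge-constrained cell-volume recovery,
per-cell morphometry, VOI summaries with replicate statistics, and
rigid + anisotropic-scale registration with XOR quantification of
incubation-induced change.

Because no raw scan volumes are publicly deposited, every stage is
validated against a synthetic tissue phantom with voxel-level ground
truth.

## The phantom: a stated world

`generate_tissue()` builds a parenchyma-like tissue from first
principles:

* **Cells** are the Voronoi regions of Poisson-disc seed points
  (minimum separation 0.7 × the target cell diameter). The seed count
  is chosen so the mean cell volume equals a sphere of
  `mean_cell_diameter`; realized equivalent diameters cluster around
  that target.
* **Airspace** is carved as interface channels: for each voxel the
  generator knows the nearest and second-nearest seed, and the gap
  `d2 − d1` is ~2× the distance to the Voronoi bisector. Channels
  (gap < 3 voxels) along randomly chosen cell–cell interfaces are
  added greedily until the target porosity is reached; the last channel
  is trimmed by bisector distance, so achieved porosity is within one
  voxel of the target (and always within the ±1-point contract checked
  by the tests). This reproduces the sheet-like intercellular channel
  morphology of real fruit tissue rather than spherical voids.
* **Contrast mode** paints every remaining interface
  `wall_thickness` = 2 voxels wide at the boundary grey level, and
  floods 60% of the air channels (channel-wise, matching the
  observation that a majority of intercellular spaces are invaded by
  the solution). Grey levels (air 5, cell 120, flooded 200, boundary
  230, vasculature 240, stone cell 210) reproduce the published
  brightness ordering; they are plausible defaults, not a calibration —
  the papers behind this workflow give no quantitative intensity scale.
* **Inclusions**: one bright tube along z (vascular strand) and
  non-overlapping compact blob clusters (brachysclereid nests).
  Placement is rejection-sampled so structures never touch each other
  or the tube — overlapping structures would merge into a single
  segmented component and make the ground truth ill-defined.
* **Noise** is additive clipped Gaussian (sd 8 grey levels by default);
  ring and reconstruction artifacts are out of scope.

All randomness flows from `random_seed`; the same spec reproduces the
phantom bit-identically.

**Scale.** Real apple/pear cells average ~160–200 µm; at 2.5 µm voxels a
desk-scale 128³ volume (320 µm) would hold ~2 such cells. The phantom's
default `mean_cell_diameter` is therefore 60 µm (24 voxels across a
cell, ~290 cells per 128³ volume): large enough for faithful shape
statistics, small enough that count-based criteria are meaningful at
desk scale. What a green phantom test establishes is that the pipeline
recovers a known tessellation under the stated noise and contrast
model; it does not establish absolute accuracy on real scans, whose
artifacts (beam hardening, rings, partial volume beyond linear
blending) the phantom deliberately omits.

## Segmentation pipeline

`run_analysis()` chains the stages in this order: classify → despeckle/
open → Sobel → watershed → **recover** → **border kill** → measure →
filter → structures → summarize.

**Classification.** `classify_intensities()` is exhaustive multi-level
Otsu (2–4 cut points over the 256-bin histogram). The enhanced-mode
pipeline uses a hierarchical variant: a 3-class fit (air / cell /
bright) followed by a second Otsu inside the bright class to separate
flooded contrast from the brighter boundary material. A flat 4-class
fit is unreliable at low porosity — with only ~2% dark voxels it
prefers splitting the dominant cell peak over isolating the air mode.

**Watershed.** Markers are regional maxima of the interior Euclidean
distance transform after h-maxima suppression (h = 2 voxels); the
flooding landscape is the inverted distance transform plus a scaled
Sobel term so watershed lines track bright boundaries. Flooding uses a
priority queue with raster-order tie-breaks: results are bit-for-bit
deterministic. Every foreground voxel receives exactly one label.

**Volume recovery.** The contrast solution marks boundaries slightly
thicker than they are, so initial cell labels are eroded by roughly the
boundary width; on 24-voxel cells that is ~20% of the volume. Recovery
is iterative geodesic label dilation (4 one-voxel steps by default)
into a growth mask consisting of the cell class plus *thin* bright
material. Three design points deserve explanation:

1. *Recovery runs before border kill, with all labels competing.* If
   only accepted labels grow, cells leak into the territory of deleted
   border neighbours, and eroded border cells fail to reach the face
   and survive the kill (a +20% interior-count bias on phantoms).
   With every label present, opposing cells split each boundary
   approximately at the bisector and border cells grow back to the
   face where they are then correctly removed.
2. *Dense-structure protection is class- and shape-based, not
   edge-based.* The voxels recovery must reclaim (boundaries) are
   themselves the strongest edges in an enhanced scan, so an
   edge-magnitude barrier cannot distinguish "stop at the vessel
   surface" from "stop at the cell boundary" — the two gradients differ
   by ~10%. Instead, compact bright components that survive a
   radius-2 opening and a size cut are off limits to cell growth.
   The Sobel ridge barrier of `recover_volume()` remains available
   (and is what a user would tune on real scans where flooded contrast
   and boundaries share grey values); the pipeline default disables it
   (`ridge_quantile = 1`).
3. *Growth is blocked at voxels claimed by another label*, so labels
   can touch but never merge, and growth is monotone.

**Border kill and filtering.** `border_kill()` deletes every label with
a voxel on any of the six VOI faces. Debris/geometry filters follow the
published per-species settings: apple 40–200 µm equivalent diameter and
sphericity > 0.75; pear no lower bound (stone cells), 200 µm upper,
sphericity > 0.75; tomato a 100 µm debris filter (the 80 µm variant
printed elsewhere in the same work is available via
`preset_filter(tomato_debris = "methods")`) with sphericity > 0.75.

**Dense structures.** Bright voxels not belonging to any segmented cell
are opened with a radius-3 ball — erasing 2-voxel boundaries and
3-voxel flooded channels while preserving vessels (radius ≥ 10 voxels)
and stone-cell nests — and grouped into 26-connected components.
Components with anisotropy > 0.9 and maximal extent > 500 µm are
vasculature; the rest, above a minimum size, are brachysclereid
clusters. Control scans have no bright class and return an empty set
with a warning, mirroring the fact that these structures cannot be
segmented without contrast.

## Morphometry

* Volume is exact voxel counting (`Σ volumes = labeled voxels × voxel
  volume`, asserted in tests).
* Equivalent spherical diameter `(6V/π)^{1/3}`; sphericity is Wadell's
  `π^{1/3}(6V)^{2/3}/A`.
* Surface area defaults to the Crofton 13-direction integral-geometry
  estimator (chord-exit counting along 3 axis, 6 face-diagonal and 4
  body-diagonal directions, weighted by spherical Voronoi measure of
  the direction set). Measured accuracy: digitized ball r = 20 −0.03%,
  cube −3.7%. A triangulated isosurface (marching tetrahedra on a
  Gaussian-smoothed field) is available as `method = "mesh"`; it is
  slightly better on smooth bodies but rounds sharp edges (cube −8.7%
  at σ = 1), which would corrupt the 0.75 sphericity cutoff for
  angular objects. Naive voxel-face counting (≈ +50% on spheres) is not
  offered.
* Anisotropy is `1 − λ_min/λ_max` over the eigenvalues of the voxel
  second-central-moment tensor (0 for isotropic bodies; a 2a:a:a
  ellipsoid gives 0.75 because moment eigenvalues scale as axis²). A
  single voxel is 0 by convention.
* VOI summaries report border-killed and filtered cell volume
  percentages, structure volume percentage, count, mean diameter and
  mean anisotropy; `summarize_replicates()` aggregates replicate VOIs
  with SEM = SD/√n (NA for a single replicate). `percent_increase()`
  is `(enhanced − control)/control × 100` to two decimals.
  `compare_groups()` computes it on group means; the per-sample
  convention can be had by applying `percent_increase()` pairwise —
  published tables are ambiguous on this point and ctmorph asserts
  neither.

The minimum representative VOI volume of 1.3 mm³ is a hard error in
`extract_voi()`; desk-scale phantom analyses pass `voi = NULL` (full
volume) or `enforce_minimum = FALSE` explicitly.

## Registration and change quantification

The pre/post-incubation comparison registers the control scan onto the
enhanced scan with a rigid + anisotropic-scale model: per-axis scaling
about the volume center, then rotation, then translation
(`p = R S (q − c) + c + t`). The metric is normalized cross-correlation
over valid (in-bounds) samples; optimization is derivative-free
(Nelder-Mead, reltol 1e-4, ≤200 iterations per level) on a 3-level
mean-pooled pyramid, preceded by an exhaustive integer translation
search at the coarsest level (±20 full-resolution voxels — the NCC
basin of textured tissue is narrower than typical incubation-induced
displacements) and followed by a full-resolution polish that
re-optimizes each axis's (translation, scale) pair jointly with a 2D
simplex: the two parameters produce nearly collinear displacement
fields and form a diagonal valley that defeats coordinate-wise and
plain simplex descent. `principal_axes_prealign()` supplies an initial
pose from mask centroids and inertia axes with a deterministic sign
convention, falling back to centroid-only alignment (with a warning)
for near-spherically-symmetric masks. A result whose final correlation
is below 0.2, or that never improves on the initial metric, is returned
with `status = "failed"` — never a silent identity.

Change is quantified by `xor_fraction()` (percent of voxels at which
the registered binary masks disagree) and
`corrected_cell_difference()`, which subtracts the fraction of the VOI
identified as airspace plus vasculature from the raw mismatch — the
correction that isolates genuine cell-volume change from material that
merely changed appearance under contrast.

A caveat established during development and worth recording: if a
synthetic "moving" scan is produced by resampling the fixed scan at the
same resolution, interpolation smoothing displaces the NCC optimum by
~0.15 voxel and ~1% scale — the nominal truth is then *not* the optimum
of the data, and no optimizer can "recover" it. Known-transform
validation therefore synthesizes both scans from a 2× supersampled
noiseless phantom with independent detector noise per scan; under that
protocol recovery is within 0.06 voxel and 0.05% scale.

## Statistics

Group comparisons are independent two-sample t tests with n = 4 VOIs
per group, pooled-variance Student by default (Welch by flag since the
published analysis does not state the variant), two-sided, significant
at p < 0.05. The degenerate zero-variance case is guarded: identical
groups give t = 0, p = 1; different constant groups give p = 0 without
a division blow-up.

## Numerical choices and degenerate inputs

* All stochastic steps live in the phantom and are seed-controlled;
  segmentation, morphometry and registration are deterministic given
  their inputs.
* 12-bit data live in 16-bit containers; `rescale_to_8bit()` maps the
  observed min–max linearly onto 0–255 with round-half-away-from-zero
  (a constant volume rescales to zeros with a warning, not an error).
* Regional-maxima detection uses greyscale reconstruction with
  ε = 10⁻³ on distance values whose smallest meaningful gaps are ~0.04.
* Empty masks: watershed returns zero labels; `surface_area()` and
  `anisotropy()` raise errors; an empty cell table writes a header-only
  CSV.
* Watershed tie-breaks, neighbor orders and label assignment in
  recovery (smallest adjacent label wins) are all fixed, so every
  pipeline output is reproducible bit-for-bit.

## Known limitations

* The phantom does not model beam hardening, ring artifacts, partial
  volume beyond linear blending, cell turgor deformation, or leaf
  geometry; conclusions about those regimes cannot be drawn from green
  tests here.
* Absolute published tissue values (analyzable-volume percentages,
  counts, mean diameters of real apple/pear/tomato VOIs) are not
  reproducible without the undeposited raw scans; the package
  reproduces the in-paper arithmetic and the direction of the
  enhancement effect on matched phantoms.
* The Crofton area estimator is slightly biased low (~4%) on bodies
  with large axis-aligned flat faces.
* Registration assumes mostly-overlapping content and moderate
  transforms (translations ≲ 20 voxels, scales within a few percent);
  it is not a deformable method.
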