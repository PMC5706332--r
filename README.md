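# ctmorph

Quantitative 3D cell morphometry for X-ray micro-CT scans of plant
tissues, with and without contrast enhancement.

## Who this is for

Micro-CT of fleshy plant tissue (apple and pear hypanthium, tomato
mesocarp) resolves micrometer anatomy, but adjacent water-filled cells
have almost no X-ray contrast: conventional workflows segment cells
only through the dark intercellular airspace, and fail progressively as
tissue porosity drops from ~20% (apple) through ~10% (pear) to ~5%
(tomato). Impregnating samples with a heavy-salt (cesium iodide)
contrast solution brightens the thin intercellular boundaries and
floods much of the airspace, making individual cells separable. ctmorph
is an open, tested implementation of the full analysis chain around
such scans, for plant physiologists and image-analysis people who want
the numbers (cell counts, sizes, shapes, analyzable-volume fractions,
incubation-induced change) out of reconstructed volumes.

## What it computes

For a volume of interest (VOI) of a reconstructed scan:

1. **Segmentation** — multi-level Otsu intensity classification
   (air / cell / contrast classes) with 3D Sobel edge assistance,
   despeckle + opening, marker-controlled 3D watershed (markers =
   h-maxima of the interior distance transform), edge-constrained
   cell-volume recovery by competitive label dilation, and removal of
   objects touching the VOI border.
2. **Morphometry** — per cell: exact voxel volume V, equivalent
   spherical diameter (6V/π)^(1/3), surface area A (Crofton
   13-direction estimator), Wadell sphericity π^(1/3)(6V)^(2/3)/A,
   anisotropy 1 − λ_min/λ_max of the second-moment tensor, centroid,
   border contact. Debris filters per species (apple 40–200 µm,
   ψ > 0.75; pear ≤200 µm, ψ > 0.75; tomato 100 µm debris filter,
   ψ > 0.75).
3. **Dense structures** — vasculature (elongated bright components) and
   brachysclereid/stone-cell clusters, separable only in enhanced
   scans.
4. **Summaries & statistics** — VOI-level analyzable-cell-volume
   percentages, counts, means, SEM across replicate VOIs, percent
   increase enhanced vs control, pooled-variance t tests (n = 4 per
   group, p < 0.05).
5. **Registration & change** — rigid + anisotropic-scale alignment of
   pre/post-incubation scans (normalized cross-correlation,
   principal-axes pre-alignment, multi-resolution), then XOR mismatch
   quantification and the non-cell correction
   `corrected_cell_difference(7.8, 1.7) = 6.1` (%).
6. **Synthetic phantoms** — `generate_tissue()` builds
   parenchyma-like tissue (Voronoi cells, interface air channels,
   contrast boundaries, flooded airspaces, vessels, stone-cell nests)
   with voxel-level ground truth and bit-reproducible seeding, so every
   stage above is validated without scan data.

## Worked example

```r
library(ctmorph)

# a contrast-enhanced synthetic tissue: 128^3 voxels at 2.5 um,
# 10% airspace (pear-like), 60 um cells, known ground truth
spec <- phantom_spec(shape = c(128, 128, 128), target_porosity = 0.10,
                     contrast_mode = TRUE, random_seed = 1)
ph <- generate_tissue(spec)
ph
#> <ctm_phantom> enhanced mode, 128 x 128 x 128 voxels @ 2.5 um
#>   290 cells, porosity 0.100 (target 0.100), 0 structures

res <- run_analysis(run_config(ph$greyscale, mode = "enhanced", seed = 1))
res$log
#>         stage                detail
#> 1       input        voxels=2097152
#> 2    classify thresholds=38/171/215
#> 3       clean        voxels=1448398
#> 4   watershed           objects=290
#> 5     recover        voxels=1868833
#> 6 border_kill           objects=102
#> 7      filter           objects=102
#> 8  structures           objects=0
unlist(res$summary)
```

The log reads: the watershed found 290 candidate cells (the phantom
contains exactly 290), 102 survive the border kill — these are the
complete, interior cells — and with no debris filter set all 102 are
retained. The ground truth has 98 interior cells, so the recovered
count is within 5%; the median per-cell volume error against the
matched truth cells is ~1.4%. `res$summary$filtered_cell_volume_pct`
(~36%) is the analyzable cell volume as a percentage of the VOI —
interior cells only, which is why it is far below the ~90% total cell
fraction of the tissue.

Control-vs-enhanced comparison on matched phantoms (the direction of
the published enhancement effect):

```r
filt <- filter_spec(d_min = 40, d_max = 200, sphericity_min = 0.75)
ctrl <- run_analysis(run_config(generate_tissue(phantom_spec(
  shape = c(96, 96, 96), target_porosity = 0.05,
  random_seed = 5))$greyscale, mode = "control", filter = filt))$summary
enh <- run_analysis(run_config(generate_tissue(phantom_spec(
  shape = c(96, 96, 96), target_porosity = 0.05, contrast_mode = TRUE,
  random_seed = 5))$greyscale, mode = "enhanced", filter = filt))$summary
c(control = ctrl$filtered_cell_volume_pct,
  enhanced = enh$filtered_cell_volume_pct)
#>  control enhanced
#>        0 19.77
```

At 5% porosity the conventional route recovers no analyzable cells at
all (the watershed cannot separate the merged tissue, and every
aggregate touches the border or fails the geometry filter), while the
contrast-enhanced route recovers ~20% of the VOI as filtered cell
volume — the qualitative behaviour reported for dense tissues.

## Command line

```sh
Rscript inst/cli/ctmorph phantom --preset pear --contrast --shape 128,128,128 --seed 1 --out out/
Rscript inst/cli/ctmorph run --input out/greyscale.tif --mode enhanced --out run1/
Rscript inst/cli/ctmorph measure --labels run1/labels.tif --out meas/
Rscript inst/cli/ctmorph compare --fixed pre.tif --moving post.tif --out cmp/
```

(After installation the launcher lives at
`system.file("cli/ctmorph", package = "ctmorph")`.)

## Conventions

Arrays are indexed `[z, y, x]` (slice, row, column; 1-based in R);
voxels are isotropic, sizes in micrometers. All randomness is
seed-controlled; segmentation and registration are deterministic given
their inputs. See the methods vignette
(`vignettes/ctmorph-methods.Rmd`) for the models, parameter defaults
and their rationale, and known limitations.
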