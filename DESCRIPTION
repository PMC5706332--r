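Package: ctmorph
Title: Cell Morphometry of Micro-CT Plant Tissue Volumes
Version: 0.1.0
Authors@R:
    person("MeBioS", "Imaging", email = "imaging@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative analysis of 3D X-ray
    micro-CT scans of plant tissues, with and without heavy-salt contrast
    enhancement. Provides multi-level Otsu intensity classification with
    3D Sobel edge assistance, despeckle/opening cleanup, marker-controlled
    3D watershed separation of cells, border-object removal, equivalent
    diameter and sphericity debris filtering, edge-constrained label
    dilation for cell-volume recovery, per-cell morphometry (volume,
    equivalent spherical diameter, isosurface area, sphericity,
    anisotropy), VOI-level summaries with replicate statistics, rigid plus
    anisotropic-scale volume registration with XOR change quantification,
    and a seeded synthetic tissue-phantom generator with voxel-level
    ground truth for validating every stage without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
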