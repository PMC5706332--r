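#' Multi-level Otsu intensity classification
#'
#' Classifies an 8-bit volume into 2-4 intensity classes by exhaustive
#' minimization of within-class variance over the 256-bin histogram (the
#' multi-level generalization of Otsu's criterion, as implemented by
#' histogram multi-thresholding modules of commercial CT software).
#' Class 0 is the darkest (airspace), the top class the brightest
#' (contrast solution / dense structures in enhanced scans).
#'
#' @param volume an 8-bit [ctm_volume()]; rescale deeper data with
#'   [rescale_to_8bit()] first.
#' @param class_count number of classes, 2-4.
#' @return an object of class `ctm_classes`: list with `data` (integer
#'   array of class ids), `thresholds` (strictly increasing intensity cut
#'   points; class k covers values in `(thresholds[k-1], thresholds[k]]`),
#'   and `n_classes`.
#' @export
classify_intensities <- function(volume, class_count = 3L) {
  stopifnot(inherits(volume, "ctm_volume"))
  if (volume$bit_depth != 8L)
    stop("classification expects 8-bit data; use rescale_to_8bit()")
  if (!class_count %in% 2:4) stop("class_count must be 2, 3 or 4")
  vals <- as.integer(round(volume$data))
  if (min(vals) == max(vals)) stop("constant volume cannot be classified")
  h <- tabulate(vals + 1L, nbins = 256L)
  cuts <- cpp_multiotsu(as.numeric(h), class_count)
  cls <- array(findInterval(vals, cuts + 0.5), dim = dim(volume$data))
  storage.mode(cls) <- "integer"
  structure(list(data = cls, thresholds = cuts,
                 n_classes = as.integer(class_count),
                 voxel_size = volume$voxel_size),
            class = "ctm_classes")
}

#' 3D Sobel gradient magnitude
#'
#' Per-voxel gradient magnitude from the three 3x3x3 Sobel kernels
#' (derivative `[-1, 0, 1]` along one axis, triangle smoothing `[1, 2, 1]`
#' along the other two); the edge map used to assist watershed separation
#' and to bound cell-volume recovery.
#'
#' @param volume a [ctm_volume()] or 3D array, at least 3 voxels per axis.
#' @return 3D numeric array of gradient magnitudes (non-negative).
#' @export
sobel_edge_magnitude <- function(volume) {
  arr <- as_vox_array(volume)
  if (any(dim(arr) < 3L)) stop("volume must be at least 3 voxels per axis")
  cpp_sobel3d(as.numeric(arr), vox_dim(arr))
}

#' Despeckle and open a binary mask
#'
#' Removes connected components (26-connectivity) smaller than
#' `min_component_voxels`, then applies binary opening with a Euclidean
#' ball structuring element of the given radius — the standard cleanup
#' between thresholding and watershed separation.
#'
#' @param binary logical 3D array (or 0/1 array).
#' @param min_component_voxels components below this size are deleted
#'   (default 27, a 3x3x3 speck).
#' @param opening_radius ball radius in voxels (0 disables opening).
#' @return logical 3D array.
#' @export
morphological_clean <- function(binary, min_component_voxels = 27L,
                                opening_radius = 1) {
  arr <- as_vox_array(binary)
  mask <- arr > 0
  d <- vox_dim(mask)
  if (min_component_voxels > 0 && any(mask)) {
    lab <- cpp_label_components(mask, d, 26L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- sizes >= min_component_voxels
    mask <- array(lab > 0L & keep[pmax(lab, 1L)], dim = d)
  }
  if (opening_radius > 0 && any(mask)) {
    r2 <- opening_radius^2
    eroded <- array(cpp_edt_sq(mask, d) > r2, dim = d)
    if (any(eroded)) {
      mask <- array(!(cpp_edt_sq(!eroded, d) > r2), dim = d)
    } else {
      mask <- eroded
    }
  }
  mask
}

#' Marker-controlled 3D watershed separation
#'
#' Splits a binary mask of merged cells into labeled objects. Markers are
#' the regional maxima of the interior Euclidean distance transform after
#' h-maxima suppression of shallow maxima (depth `h` voxels); the flooding
#' landscape is the inverted distance transform, optionally augmented
#' with a scaled edge-magnitude term so that watershed lines track bright
#' contrast boundaries. Flooding order is deterministic (priority queue
#' with raster-order tie-break), every masked voxel receives exactly one
#' label, and labels are 26-connected.
#'
#' @param binary logical 3D array of the cell class.
#' @param edge_map optional 3D edge-magnitude array (e.g. from
#'   [sobel_edge_magnitude()]).
#' @param h depth parameter for maxima suppression, voxels (default 2).
#' @param edge_weight weight of the edge term relative to the distance
#'   term after scaling both to a common range (default 1).
#' @param voxel_size voxel size recorded on the output labels.
#' @return a [ctm_labels()].
#' @export
watershed_separate <- function(binary, edge_map = NULL, h = 2,
                               edge_weight = 1, voxel_size = 1) {
  mask <- as_vox_array(binary) > 0
  d <- vox_dim(mask)
  if (!any(mask))
    return(ctm_labels(array(0L, dim(mask)), voxel_size))
  dist <- sqrt(cpp_edt_sq(mask, d))
  hmax <- cpp_reconstruct_gray(pmax(dist - h, 0), dist, d)
  eps <- 1e-3
  rec <- cpp_reconstruct_gray(pmax(hmax - eps, 0), hmax, d)
  maxima <- array((hmax - rec) >= eps / 2 & mask, dim = d)
  markers <- cpp_label_components(maxima, d, 26L)
  landscape <- -dist
  if (!is.null(edge_map)) {
    em <- as_vox_array(edge_map)
    emax <- max(em)
    if (emax > 0)
      landscape <- landscape + edge_weight * (em / emax) * max(dist)
  }
  lab <- cpp_watershed(as.numeric(landscape), markers, mask, d, 26L)
  ctm_labels(array(lab, dim = d), voxel_size)
}

#' Remove labeled objects touching the VOI border
#'
#' Deletes every label owning at least one voxel on any of the six faces
#' of the volume (incomplete objects cut by the VOI); interior labels are
#' left unchanged, keeping their ids.
#'
#' @param labels a [ctm_labels()].
#' @return a [ctm_labels()] with border objects set to 0.
#' @export
border_kill <- function(labels) {
  stopifnot(inherits(labels, "ctm_labels"))
  d <- vox_dim(labels$data)
  nmax <- max(labels$data)
  if (nmax == 0L) return(labels)
  st <- cpp_region_stats(labels$data, d)
  map <- ifelse(st$touches_border, 0L, seq_len(nmax))
  out <- cpp_relabel(labels$data, as.integer(map))
  ctm_labels(array(out, dim = d), labels$voxel_size)
}

#' Debris / geometry filter specification
#'
#' Bounds on equivalent spherical diameter and sphericity used to discard
#' debris, implausibly large cell clusters and geometrically unlikely
#' objects. Species presets used in fruit-tissue work: apple 40-200 um
#' with sphericity > 0.75; pear upper bound 200 um only (stone cells
#' forbid a lower filter), sphericity > 0.75; tomato 100 um debris filter
#' with sphericity > 0.75 (an 80 um variant is in circulation for the
#' same tissue; both are available via [preset_filter()]).
#'
#' @param d_min,d_max equivalent-diameter bounds in micrometers, or NULL.
#' @param sphericity_min objects must exceed this sphericity, or NULL.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(d_min = NULL, d_max = NULL, sphericity_min = NULL) {
  if (!is.null(d_min) && !is.null(d_max) && !(d_min < d_max))
    stop("d_min must be < d_max")
  if (!is.null(d_min) && d_min <= 0) stop("d_min must be positive")
  if (!is.null(sphericity_min) &&
      (sphericity_min < 0 || sphericity_min > 1))
    stop("sphericity_min must be in [0, 1]")
  structure(list(d_min = d_min, d_max = d_max,
                 sphericity_min = sphericity_min), class = "filter_spec")
}

#' Species filter presets
#'
#' @param preset `"apple"`, `"pear"` or `"tomato"`.
#' @param tomato_debris which published tomato debris-filter value to
#'   use: `"results"` (100 um) or `"methods"` (80 um).
#' @return a [filter_spec()].
#' @export
preset_filter <- function(preset = c("apple", "pear", "tomato"),
                          tomato_debris = c("results", "methods")) {
  preset <- match.arg(preset)
  tomato_debris <- match.arg(tomato_debris)
  switch(preset,
         apple = filter_spec(d_min = 40, d_max = 200, sphericity_min = 0.75),
         pear = filter_spec(d_min = NULL, d_max = 200, sphericity_min = 0.75),
         tomato = filter_spec(
           d_min = if (tomato_debris == "results") 100 else 80,
           d_max = NULL, sphericity_min = 0.75))
}

#' Apply a debris/geometry filter to measured cells
#'
#' Keeps exactly the records with `d_min <= equivalent diameter <= d_max`
#' (absent bounds are skipped) and `sphericity > sphericity_min`.
#' Idempotent; output rows are a subset of input rows.
#'
#' @param cells data frame from [measure_labels()].
#' @param spec a [filter_spec()].
#' @return the filtered data frame.
#' @export
apply_filters <- function(cells, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!nrow(cells)) return(cells)
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(spec$d_min))
    keep <- keep & cells$equivalent_diameter_um >= spec$d_min
  if (!is.null(spec$d_max))
    keep <- keep & cells$equivalent_diameter_um <= spec$d_max
  if (!is.null(spec$sphericity_min))
    keep <- keep & cells$sphericity > spec$sphericity_min
  cells[keep, , drop = FALSE]
}

#' Recover lost cell volume by edge-constrained label dilation
#'
#' Contrast solution marks cell boundaries slightly thicker than they
#' are, so the initially segmented cells are eroded versions of the true
#' ones. Each label grows by iterative one-voxel geodesic dilation
#' restricted to `cell_mask`, blocked at voxels whose edge magnitude
#' exceeds a ridge threshold (the Sobel reference) and at voxels already
#' claimed by another label. Labels never merge and growth is monotone.
#'
#' @param labels a [ctm_labels()].
#' @param cell_mask logical array of voxels cells may grow into.
#' @param edge_map edge-magnitude array (e.g. [sobel_edge_magnitude()]).
#' @param max_iterations dilation steps (0 = identity).
#' @param ridge_quantile quantile of nonzero edge magnitudes used as the
#'   blocking threshold (default 0.75).
#' @return a [ctm_labels()] with dilated labels.
#' @export
recover_volume <- function(labels, cell_mask, edge_map, max_iterations = 3L,
                           ridge_quantile = 0.75) {
  stopifnot(inherits(labels, "ctm_labels"))
  if (max_iterations == 0L) return(labels)
  mask <- as_vox_array(cell_mask) > 0
  em <- as_vox_array(edge_map)
  d <- vox_dim(labels$data)
  nz <- em[em > 0]
  thr <- if (length(nz)) stats::quantile(nz, ridge_quantile, names = FALSE)
         else Inf
  barrier <- array(em >= thr, dim = d)
  out <- cpp_geodesic_label_dilate(labels$data, mask, barrier, d,
                                   as.integer(max_iterations))
  ctm_labels(array(out, dim = d), labels$voxel_size)
}

#' Extract bright dense structures (vasculature, stone-cell clusters)
#'
#' Groups bright voxels (any class above the cell class) that do not
#' belong to accepted cells into candidate structures. Thin bright
#' material — contrast-marked cell boundaries and flooded intercellular
#' channels, both only a few voxels wide — is removed by a binary opening
#' before grouping, leaving the compact dense structures. Elongated
#' components (anisotropy > 0.9 and maximal extent >
#' `vasculature_min_extent`) are classed as vasculature; the remaining
#' components above a minimum size are classed as brachysclereid
#' (stone-cell) clusters. Control scans have no bright class, matching
#' the inability to segment these structures without contrast: the
#' result is empty, with a warning.
#'
#' @param classes a `ctm_classes` from [classify_intensities()].
#' @param labels accepted cell labels ([ctm_labels()]) whose voxels are
#'   excluded, or NULL.
#' @param voxel_size micrometers per voxel.
#' @param min_component_voxels discard smaller opened bright components
#'   (default 500; residual boundary-junction lumps are a few hundred
#'   voxels at typical resolutions, real structures orders larger).
#' @param opening_radius ball radius (voxels) of the thin-material
#'   opening (default 3, enough to erase 2-voxel boundaries and flooded
#'   intercellular channels while keeping vessels and stone-cell nests).
#' @param vasculature_min_extent minimal maximal extent (um) for the
#'   vasculature class (default 500).
#' @param vasculature_min_anisotropy anisotropy cut for vasculature.
#' @return list with `labels` (a [ctm_labels()] of structures) and
#'   `records` (data frame: label, class, volume_um3, anisotropy,
#'   max_extent_um, volume_pct of the VOI).
#' @export
extract_dense_structures <- function(classes, labels = NULL,
                                     voxel_size = NULL,
                                     min_component_voxels = 500L,
                                     opening_radius = 3,
                                     vasculature_min_extent = 500,
                                     vasculature_min_anisotropy = 0.9) {
  stopifnot(inherits(classes, "ctm_classes"))
  vs <- voxel_size %||% classes$voxel_size
  d <- vox_dim(classes$data)
  empty <- list(labels = ctm_labels(array(0L, dim(classes$data)), vs),
                records = data.frame(
                  label = integer(0), class = character(0),
                  volume_um3 = numeric(0), anisotropy = numeric(0),
                  max_extent_um = numeric(0), volume_pct = numeric(0)))
  if (classes$n_classes < 3L || max(classes$data) < 2L) {
    warning("no bright intensity class: dense structures are not ",
            "separable in control scans")
    return(empty)
  }
  bright <- classes$data >= 2L
  if (!is.null(labels)) bright <- bright & labels$data == 0L
  bright <- morphological_clean(array(bright, dim = dim(classes$data)),
                                0L, opening_radius)
  if (!any(bright)) return(empty)
  comp <- cpp_label_components(array(bright, dim = dim(classes$data)),
                               d, 26L)
  st <- cpp_region_stats(comp, d)
  recs <- list()
  keep_map <- integer(max(comp))
  nxt <- 0L
  for (k in seq_along(st$count)) {
    n <- st$count[k]
    if (n < min_component_voxels) next
    mom <- label_moments(st, k)
    aniso <- anisotropy_from_cov(mom$cov)
    bb <- st$bbox[k, ]
    extent <- sqrt(sum(((bb[c(2, 4, 6)] - bb[c(1, 3, 5)]) + 1)^2)) * vs
    cls <- if (aniso > vasculature_min_anisotropy &&
               extent > vasculature_min_extent) "vasculature"
           else "brachysclereid"
    nxt <- nxt + 1L
    keep_map[k] <- nxt
    recs[[nxt]] <- data.frame(
      label = nxt, class = cls, volume_um3 = n * vs^3,
      anisotropy = aniso, max_extent_um = extent,
      volume_pct = 100 * n / prod(d))
  }
  if (!nxt) return(empty)
  out <- cpp_relabel(comp, keep_map)
  list(labels = ctm_labels(array(out, dim = dim(classes$data)), vs),
       records = do.call(rbind, recs))
}
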