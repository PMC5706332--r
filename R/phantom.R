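#' Specification of a synthetic tissue phantom
#'
#' Parameterizes a synthetic parenchyma-like tissue volume with known
#' voxel-level ground truth, emulating what a micro-CT scan of fleshy
#' fruit tissue looks like before ("control") and after contrast
#' enhancement ("enhanced"): near-black intercellular airspace, mid-grey
#' cells, and — in contrast mode — thin bright intercellular boundaries
#' plus contrast-flooded airspaces, optionally with a bright vascular
#' strand and dense stone-cell clusters.
#'
#' Default grey levels follow the qualitative brightness ordering of
#' contrast-enhanced scans (air black, cells dark grey, boundaries and
#' flooded spaces light grey to white); they are plausible values, not a
#' calibration. The default boundary width is 2 voxels, the width
#' contrast-marked cell interfaces effectively have at 2.5-3 um
#' resolution.
#'
#' @param shape voxels per axis, `(nz, ny, nx)`; each >= 32.
#' @param voxel_size voxel edge in micrometers.
#' @param target_porosity intercellular air fraction in `[0, 0.5)`.
#'   Porosity presets for the three tissue archetypes: apple 0.20,
#'   pear 0.10, tomato 0.05 (see [phantom_preset()]).
#' @param mean_cell_diameter target equivalent cell diameter in
#'   micrometers; the tessellation seed count is chosen so the mean cell
#'   volume matches a sphere of this diameter.
#' @param wall_thickness width of the painted contrast boundary, voxels.
#' @param intensity_levels named list of grey levels (0-255): `air`,
#'   `cell`, `contrast_boundary`, `flooded_airspace`, `vasculature`,
#'   `stone_cell`.
#' @param noise_sd standard deviation of additive Gaussian imaging noise
#'   (grey levels); applied by [generate_tissue()].
#' @param contrast_mode logical; paint bright cell boundaries and flood a
#'   fraction of the airspace.
#' @param flooded_fraction fraction of airspace voxels repainted at the
#'   flooded level in contrast mode (a majority of intercellular spaces
#'   is typically invaded by the solution; default 0.6).
#' @param include_vasculature,include_stone_cells add bright inclusions
#'   via [add_inclusions()] (contrast mode only).
#' @param random_seed integer seed; the same spec and seed reproduce the
#'   phantom bit-identically.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         voxel_size = 2.5,
                         target_porosity = 0.10,
                         mean_cell_diameter = 60,
                         wall_thickness = 2,
                         intensity_levels = list(
                           air = 5, cell = 120, contrast_boundary = 230,
                           flooded_airspace = 200, vasculature = 240,
                           stone_cell = 210),
                         noise_sd = 8,
                         contrast_mode = FALSE,
                         flooded_fraction = 0.6,
                         include_vasculature = FALSE,
                         include_stone_cells = FALSE,
                         random_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("`shape` must be three integers, each >= 32")
  if (target_porosity < 0 || target_porosity >= 0.5)
    stop("`target_porosity` must be in [0, 0.5)")
  if (wall_thickness < 1) stop("`wall_thickness` must be >= 1 voxel")
  lv <- intensity_levels
  need <- c("air", "cell", "contrast_boundary", "flooded_airspace",
            "vasculature", "stone_cell")
  if (!all(need %in% names(lv)))
    stop("intensity_levels must name: ", paste(need, collapse = ", "))
  if (any(unlist(lv) < 0) || any(unlist(lv) > 255))
    stop("intensity levels must be within [0, 255]")
  if (contrast_mode &&
      !(lv$contrast_boundary > lv$cell && lv$cell > lv$air))
    stop("contrast mode requires contrast_boundary > cell > air")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (flooded_fraction < 0 || flooded_fraction > 1)
    stop("`flooded_fraction` must be in [0, 1]")
  if (mean_cell_diameter / voxel_size < 6)
    stop("mean_cell_diameter must span at least ~6 voxels")
  structure(list(shape = shape, voxel_size = voxel_size,
                 target_porosity = target_porosity,
                 mean_cell_diameter = mean_cell_diameter,
                 wall_thickness = wall_thickness,
                 intensity_levels = lv, noise_sd = noise_sd,
                 contrast_mode = contrast_mode,
                 flooded_fraction = flooded_fraction,
                 include_vasculature = include_vasculature,
                 include_stone_cells = include_stone_cells,
                 random_seed = as.integer(random_seed)),
            class = "phantom_spec")
}

#' Phantom presets for the three tissue archetypes
#'
#' Porosity presets: apple 20%, pear 10%, tomato 5% intercellular air.
#'
#' @param preset one of `"apple"`, `"pear"`, `"tomato"`.
#' @param ... overrides passed on to [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("apple", "pear", "tomato"), ...) {
  preset <- match.arg(preset)
  porosity <- c(apple = 0.20, pear = 0.10, tomato = 0.05)[[preset]]
  args <- list(...)
  args$target_porosity <- args$target_porosity %||% porosity
  do.call(phantom_spec, args)
}

# Poisson-disc (dart-throwing) seed points: uniform candidates accepted if
# at least `min_sep` voxels from every accepted point, until `n_target`
# points or the attempt budget is exhausted.
poisson_disc_seeds <- function(shape, n_target, min_sep) {
  pts <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  budget <- 60L * n_target
  while (nrow(pts) < n_target && attempts < budget) {
    attempts <- attempts + 1L
    cand <- runif(3, min = 0, max = shape - 1)
    if (nrow(pts)) {
      dd <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
        (pts[, 3] - cand[3])^2
      if (min(dd) < min_sep^2) next
    }
    pts <- rbind(pts, cand)
  }
  pts
}

#' Generate a synthetic tissue volume with ground truth
#'
#' Cells are a Voronoi-like tessellation of Poisson-disc seed points
#' (minimum separation 0.7 x the target cell diameter), so realized cell
#' volumes cluster around the target. Intercellular airspace is carved as
#' channels along randomly chosen cell-cell interfaces, greedily until
#' the air fraction reaches the target porosity (the last channel is
#' trimmed, so the achieved fraction is within one voxel of the target).
#' In contrast mode every remaining cell-cell interface is painted
#' `wall_thickness` voxels wide at the boundary grey level and a fraction
#' of the air channels is flooded at the flooded grey level. Imaging
#' noise (additive clipped Gaussian) is applied last. All randomness
#' derives from `spec$random_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `ctm_phantom`: a list with elements
#'   `greyscale` ([ctm_volume()]), `truth_labels` ([ctm_labels()], one
#'   label per cell; interface voxels belong to the nearest cell),
#'   `truth_air` (logical array), `truth_structures` ([ctm_labels()]),
#'   `structure_classes` (character, per structure label),
#'   `truth_classes` (integer array: 0 dark air, 1 cell grey, 2 bright),
#'   `achieved_porosity`, and `spec`.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  nvox <- prod(shape)
  dvox <- spec$mean_cell_diameter / spec$voxel_size
  lv <- spec$intensity_levels

  out <- with_seed(spec$random_seed, {
    n_target <- max(2L, round(nvox / (pi / 6 * dvox^3)))
    seeds <- poisson_disc_seeds(shape, n_target, 0.7 * dvox)
    if (nrow(seeds) < n_target)
      warning(sprintf(
        "Poisson-disc sampling saturated at %d of %d seeds; cells will run large",
        nrow(seeds), n_target))
    nn <- cpp_nearest_two_seeds(seeds, shape)
    labels <- nn$id1
    gap <- nn$d2 - nn$d1  # ~2x distance to the Voronoi bisector

    # candidate interface channels, keyed by unordered seed pair
    w_air <- 3  # air channel width, voxels
    cand <- which(gap < w_air)
    pair_key <- paste(pmin(nn$id1[cand], nn$id2[cand]),
                      pmax(nn$id1[cand], nn$id2[cand]))
    channels <- split(cand, pair_key)

    air <- logical(nvox)
    target_vox <- round(spec$target_porosity * nvox)
    used_channels <- list()
    if (target_vox > 0) {
      ord <- sample(length(channels))
      cur <- 0L
      for (ci in ord) {
        if (cur >= target_vox) break
        ch <- channels[[ci]]
        ch <- ch[!air[ch]]
        needed <- target_vox - cur
        if (length(ch) > needed) {
          ch <- ch[order(gap[ch])][seq_len(needed)]
        }
        air[ch] <- TRUE
        cur <- cur + length(ch)
        used_channels[[length(used_channels) + 1L]] <- ch
      }
      if (cur < target_vox * 0.99 - 1)
        warning(sprintf(
          "target porosity %.3f unreachable for this geometry; achieved %.3f",
          spec$target_porosity, cur / nvox))
    }
    achieved <- sum(air) / nvox
    labels[air] <- 0L  # truth masks are pairwise disjoint

    grey <- rep(lv$cell, nvox)
    grey[air] <- lv$air
    classes <- rep(1L, nvox)
    classes[air] <- 0L

    if (spec$contrast_mode) {
      wall <- gap < spec$wall_thickness & !air
      grey[wall] <- lv$contrast_boundary
      classes[wall] <- 2L
      if (length(used_channels) && spec$flooded_fraction > 0) {
        flood_target <- spec$flooded_fraction * sum(air)
        ford <- sample(length(used_channels))
        flooded <- 0L
        for (ci in ford) {
          if (flooded >= flood_target) break
          ch <- used_channels[[ci]]
          grey[ch] <- lv$flooded_airspace
          classes[ch] <- 2L
          flooded <- flooded + length(ch)
        }
      }
    }

    dim(grey) <- shape
    dim(classes) <- shape
    dim(air) <- shape
    phantom <- structure(list(
      greyscale = ctm_volume(array(grey, shape), spec$voxel_size, 8L),
      truth_labels = ctm_labels(labels, spec$voxel_size),
      truth_air = air,
      truth_structures = ctm_labels(array(0L, shape), spec$voxel_size),
      structure_classes = character(0),
      truth_classes = classes,
      achieved_porosity = achieved,
      spec = spec), class = "ctm_phantom")

    if (spec$include_vasculature || spec$include_stone_cells) {
      phantom <- add_inclusions(
        phantom,
        vessel_radius = if (spec$include_vasculature) 25 else 0,
        cluster_diameter = if (spec$include_stone_cells) 150 else 0)
    }
    phantom
  })

  if (spec$noise_sd > 0) {
    out$greyscale <- add_imaging_noise(out$greyscale, spec$noise_sd,
                                       seed = spec$random_seed + 1000L)
  }
  out
}

#' Add clipped Gaussian imaging noise to a volume
#'
#' Additive zero-mean Gaussian noise of the given standard deviation,
#' clipped to the volume's valid intensity range; stands in for detector
#' noise that a reconstruction pipeline would otherwise contribute.
#'
#' @param volume a [ctm_volume()].
#' @param noise_sd noise standard deviation in grey levels (>= 0).
#' @param seed integer seed; fixed seed gives identical output.
#' @return a noisy [ctm_volume()].
#' @export
add_imaging_noise <- function(volume, noise_sd, seed = 1L) {
  stopifnot(inherits(volume, "ctm_volume"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (noise_sd == 0) return(volume)
  hi <- 2^volume$bit_depth - 1
  noisy <- with_seed(seed, {
    volume$data + rnorm(length(volume$data), sd = noise_sd)
  })
  noisy <- pmin(pmax(round(noisy), 0), hi)
  dim(noisy) <- dim(volume$data)
  ctm_volume(noisy, volume$voxel_size, volume$bit_depth)
}

#' Paint bright inclusions (vasculature, stone-cell clusters) into a phantom
#'
#' Adds one bright tube traversing the volume along z (the vascular
#' strand) and/or a number of compact bright blob clusters (the
#' brachysclereid / stone-cell nests of pear flesh). Inclusions are only
#' separable from cells in contrast-enhanced scans, so `contrast_mode`
#' must be on. Structure voxels are removed from the cell and air truth
#' so that the truth masks stay pairwise disjoint.
#'
#' @param phantom a `ctm_phantom` from [generate_tissue()].
#' @param vessel_radius tube radius in micrometers (0 = no tube).
#' @param cluster_diameter stone-cell cluster diameter in micrometers
#'   (0 = no clusters).
#' @param n_clusters number of clusters.
#' @return the phantom with updated greyscale, truths and
#'   `structure_classes`.
#' @export
add_inclusions <- function(phantom, vessel_radius = 25,
                           cluster_diameter = 150, n_clusters = 3L) {
  stopifnot(inherits(phantom, "ctm_phantom"))
  spec <- phantom$spec
  if (!spec$contrast_mode)
    stop("inclusions are only separable in contrast mode")
  shape <- spec$shape
  vs <- spec$voxel_size
  lv <- spec$intensity_levels
  grey <- phantom$greyscale$data
  structures <- phantom$truth_structures$data
  classes <- phantom$truth_classes
  struct_classes <- phantom$structure_classes
  next_label <- max(structures) + 1L

  # voxel center coordinates, 0-based (z, y, x)
  idx <- seq_len(prod(shape)) - 1L
  z <- idx %% shape[1]
  y <- (idx %/% shape[1]) %% shape[2]
  x <- idx %/% (shape[1] * shape[2])

  if (vessel_radius > 0) {
    rv <- vessel_radius / vs
    if (2 * rv + 4 > min(shape[2], shape[3]))
      stop("vessel does not fit inside the volume")
    cyv <- runif(1, rv + 2, shape[2] - 1 - rv - 2)
    cxv <- runif(1, rv + 2, shape[3] - 1 - rv - 2)
    inside <- (y - cyv)^2 + (x - cxv)^2 <= rv^2
    grey[inside] <- lv$vasculature
    structures[inside] <- next_label
    classes[inside] <- 2L
    struct_classes <- c(struct_classes, "vasculature")
    names(struct_classes)[length(struct_classes)] <- next_label
    next_label <- next_label + 1L
  }

  if (cluster_diameter > 0 && n_clusters > 0) {
    rc <- cluster_diameter / (2 * vs)
    if (any(2 * rc + 4 > shape))
      stop("stone-cell cluster does not fit inside the volume")
    placed <- matrix(numeric(0), ncol = 3)
    for (k in seq_len(n_clusters)) {
      # rejection sampling: clusters must not touch each other or the
      # vessel, or they would merge into one segmented component
      ok <- FALSE
      for (try in seq_len(200L)) {
        cz <- runif(1, rc + 2, shape[1] - 1 - rc - 2)
        cy <- runif(1, rc + 2, shape[2] - 1 - rc - 2)
        cx <- runif(1, rc + 2, shape[3] - 1 - rc - 2)
        clear_tube <- vessel_radius <= 0 ||
          sqrt((cy - cyv)^2 + (cx - cxv)^2) >
            rc + vessel_radius / vs + 3
        clear_peers <- !nrow(placed) ||
          min(sqrt((placed[, 1] - cz)^2 + (placed[, 2] - cy)^2 +
                     (placed[, 3] - cx)^2)) > 2 * rc + 3
        if (clear_tube && clear_peers) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place ", n_clusters,
             " non-overlapping stone-cell clusters in this volume")
      placed <- rbind(placed, c(cz, cy, cx))
      # compact blob: union of a few overlapping balls around the center
      inside <- logical(length(idx))
      for (b in seq_len(5)) {
        off <- runif(3, -rc / 3, rc / 3)
        rb <- rc * runif(1, 0.6, 0.85)
        inside <- inside |
          ((z - cz - off[1])^2 + (y - cy - off[2])^2 +
             (x - cx - off[3])^2 <= rb^2)
      }
      inside <- inside & structures == 0L
      grey[inside] <- lv$stone_cell
      structures[inside] <- next_label
      classes[inside] <- 2L
      struct_classes <- c(struct_classes, "brachysclereid")
      names(struct_classes)[length(struct_classes)] <- next_label
      next_label <- next_label + 1L
    }
  }

  smask <- structures > 0L
  labels <- phantom$truth_labels$data
  labels[smask] <- 0L
  air <- phantom$truth_air
  air[smask] <- FALSE

  phantom$greyscale <- ctm_volume(grey, vs, phantom$greyscale$bit_depth)
  phantom$truth_labels <- ctm_labels(labels, vs)
  phantom$truth_air <- air
  phantom$truth_structures <- ctm_labels(structures, vs)
  phantom$truth_classes <- classes
  phantom$structure_classes <- struct_classes
  phantom$achieved_porosity <- sum(air) / prod(shape)
  phantom
}

#' @export
print.ctm_phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<ctm_phantom> %s mode, %d x %d x %d voxels @ %g um\n",
    if (s$contrast_mode) "enhanced" else "control",
    s$shape[1], s$shape[2], s$shape[3], s$voxel_size))
  cat(sprintf("  %d cells, porosity %.3f (target %.3f), %d structures\n",
              max(x$truth_labels$data), x$achieved_porosity,
              s$target_porosity, max(x$truth_structures$data)))
  invisible(x)
}
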