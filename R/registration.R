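#' Rigid + anisotropic-scale transform
#'
#' Parameterizes the map from fixed-grid voxel coordinates to moving-grid
#' voxel coordinates: `p = R(angles) S(scale) (q - center) + center +
#' translation`, i.e. per-axis scaling about the volume center applied
#' before rotation, followed by translation. All lengths are in voxels of
#' the common grid; `scale` is dimensionless per axis `(z, y, x)`.
#'
#' @param rotation three rotation angles in radians (about the z, y, x
#'   axes, applied in that order).
#' @param translation voxel triple.
#' @param scale positive per-axis scale triple.
#' @param center voxel triple the rotation/scaling pivots about.
#' @param final_metric correlation achieved by registration (NA before).
#' @param status `"init"`, `"converged"` or `"failed"`.
#' @return an object of class `ctm_transform`.
#' @export
ctm_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                          scale = c(1, 1, 1), center = c(0, 0, 0),
                          final_metric = NA_real_, status = "init") {
  if (any(scale <= 0)) stop("scales must be positive")
  structure(list(rotation = rotation, translation = translation,
                 scale = scale, center = center,
                 final_metric = final_metric, status = status),
            class = "ctm_transform")
}

# Rotation matrix about the three grid axes (axis 1 = z, 2 = y, 3 = x in
# array-index order), composed R = R1 R2 R3.
rotation_matrix <- function(angles) {
  r1 <- angles[1]; r2 <- angles[2]; r3 <- angles[3]
  R1 <- matrix(c(1, 0, 0,
                 0, cos(r1), -sin(r1),
                 0, sin(r1), cos(r1)), 3, 3, byrow = TRUE)
  R2 <- matrix(c(cos(r2), 0, sin(r2),
                 0, 1, 0,
                 -sin(r2), 0, cos(r2)), 3, 3, byrow = TRUE)
  R3 <- matrix(c(cos(r3), -sin(r3), 0,
                 sin(r3), cos(r3), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R1 %*% R2 %*% R3
}

# Affine (A, b) form of a transform: p = A q + b.
transform_affine <- function(tr) {
  A <- rotation_matrix(tr$rotation) %*% diag(tr$scale)
  b <- tr$center + tr$translation - A %*% tr$center
  list(A = A, b = as.numeric(b))
}

#' Invert a transform (affine form)
#'
#' Returns the affine `(A, b)` of the inverse map; applying a transform
#' and then its inverse is the identity to numerical tolerance.
#'
#' @param tr a [ctm_transform()].
#' @return list with matrix `A` and vector `b`.
#' @export
invert_transform <- function(tr) {
  af <- transform_affine(tr)
  Ai <- solve(af$A)
  list(A = Ai, b = as.numeric(-Ai %*% af$b))
}

#' Resample a volume under a transform
#'
#' Samples the moving volume on the fixed grid: output voxel `q` takes
#' the moving intensity at `p = A q + b`. Trilinear interpolation for
#' greyscale, nearest-neighbor for labels (preserving binarity).
#'
#' @param moving a [ctm_volume()] or [ctm_labels()].
#' @param transform a [ctm_transform()] or an affine list `(A, b)`.
#' @param out_dim output grid dimensions (default: moving's).
#' @param fill value for out-of-bounds samples.
#' @return same class as `moving`.
#' @export
apply_transform <- function(moving, transform, out_dim = NULL, fill = 0) {
  af <- if (inherits(transform, "ctm_transform"))
    transform_affine(transform) else transform
  arr <- as_vox_array(moving)
  out_dim <- as.integer(out_dim %||% dim(arr))
  nearest <- inherits(moving, "ctm_labels")
  res <- cpp_affine_resample(as.numeric(arr), vox_dim(arr), out_dim,
                             af$A, af$b, nearest, fill)
  if (nearest)
    ctm_labels(array(as.integer(round(res)), out_dim), moving$voxel_size)
  else
    ctm_volume(array(pmin(pmax(res, 0), 2^moving$bit_depth - 1), out_dim),
               moving$voxel_size, moving$bit_depth)
}

#' Principal-axes pre-alignment
#'
#' Initializes registration by mapping the fixed mask's centroid and
#' principal inertia axes onto the moving mask's (the direction that
#' resampling needs). Eigenvector signs follow a deterministic
#' convention (largest-magnitude component positive, right-handed).
#' A degenerate, near-spherically-symmetric mass distribution cannot
#' orient the axes: alignment falls back to centroids only, with a
#' warning.
#'
#' @param fixed,moving logical 3D arrays (non-empty masks).
#' @param degeneracy_tol relative eigenvalue spread below which the
#'   distribution counts as degenerate (default 0.02).
#' @return a [ctm_transform()].
#' @export
principal_axes_prealign <- function(fixed, moving, degeneracy_tol = 0.02) {
  fm <- as_vox_array(fixed) > 0
  mm <- as_vox_array(moving) > 0
  if (!any(fm) || !any(mm)) stop("masks must be non-empty")
  stats_of <- function(m) {
    lab <- array(as.integer(m), dim = dim(m))
    st <- cpp_region_stats(lab, vox_dim(m))
    label_moments(st, 1L)
  }
  sf <- stats_of(fm)
  sm <- stats_of(mm)
  spread <- function(cov) {
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    (max(ev) - min(ev)) / max(ev)
  }
  center <- sf$centroid
  if (spread(sf$cov) < degeneracy_tol || spread(sm$cov) < degeneracy_tol) {
    warning("near-isotropic mass distribution: centroid-only pre-alignment")
    return(ctm_transform(translation = sm$centroid - sf$centroid,
                         center = center, status = "init"))
  }
  axes <- function(cov) {
    e <- eigen(cov, symmetric = TRUE)
    V <- e$vectors  # columns ordered by decreasing eigenvalue
    for (j in 1:3) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    V
  }
  Vf <- axes(sf$cov)
  Vm <- axes(sm$cov)
  R <- Vm %*% t(Vf)  # fixed frame -> moving frame
  tr <- ctm_transform(center = center, status = "init")
  # store as explicit affine: p = R (q - cf) + cm
  af <- list(A = R, b = as.numeric(sm$centroid - R %*% sf$centroid))
  tr$rotation <- rotation_angles_from_matrix(R)
  tr$translation <- as.numeric(af$b + R %*% center - center)
  tr
}

# Euler angles (z, y, x convention of rotation_matrix) from a rotation
# matrix.
rotation_angles_from_matrix <- function(R) {
  r2 <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(r2)) > 1e-8) {
    r1 <- atan2(-R[2, 3], R[3, 3])
    r3 <- atan2(-R[1, 2], R[1, 1])
  } else {
    r1 <- atan2(R[3, 2], R[2, 2])
    r3 <- 0
  }
  c(r1, r2, r3)
}

# Normalized cross-correlation between two equal-length vectors.
ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid + anisotropic-scale registration
#'
#' Local optimization of normalized cross-correlation over rotation,
#' translation and per-axis scale, on a 3-level multi-resolution pyramid
#' (mean-pooled by 2). Optimization is derivative-free (Nelder-Mead) on
#' a delta transform composed with the initialization, with convergence
#' tolerance 1e-4 and at most `max_iter` iterations per level. Returns a
#' failure status when the content does not overlap or the metric failed
#' to improve; the result is never a silent identity.
#'
#' @param fixed,moving [ctm_volume()]s on grids of equal voxel size.
#' @param init optional initial [ctm_transform()] (e.g. from
#'   [principal_axes_prealign()]).
#' @param levels pyramid levels (default 3).
#' @param max_iter Nelder-Mead iterations per level (default 200).
#' @param capture_range half-width, in full-resolution voxels, of the
#'   exhaustive translation search at the coarsest level (default 20).
#' @param min_metric final correlation below which the result is flagged
#'   as a failure (default 0.2).
#' @return list with `transform` (a [ctm_transform()], `status` and
#'   `final_metric` filled in), `metric`, and `resampled` (moving
#'   resampled onto the fixed grid).
#' @export
register_volumes <- function(fixed, moving, init = NULL, levels = 3L,
                             max_iter = 200L, capture_range = 20L,
                             min_metric = 0.2) {
  stopifnot(inherits(fixed, "ctm_volume"), inherits(moving, "ctm_volume"))
  center <- (dim(fixed$data) - 1) / 2
  if (is.null(init)) init <- ctm_transform(center = center)
  af_init <- transform_affine(init)

  pyr_f <- list(as.numeric(fixed$data))
  pyr_m <- list(as.numeric(moving$data))
  dim_f <- list(vox_dim(fixed$data))
  dim_m <- list(vox_dim(moving$data))
  for (l in seq_len(levels - 1)) {
    if (any(dim_f[[l]] < 16L) || any(dim_m[[l]] < 16L)) break
    pyr_f[[l + 1]] <- cpp_downsample2(pyr_f[[l]], dim_f[[l]])
    dim_f[[l + 1]] <- vox_dim(pyr_f[[l + 1]])
    pyr_m[[l + 1]] <- cpp_downsample2(pyr_m[[l]], dim_m[[l]])
    dim_m[[l + 1]] <- vox_dim(pyr_m[[l + 1]])
  }
  nlev <- length(pyr_f)

  # delta parameters: 3 angles, 3 translations (voxels), 3 log-scales
  full_affine <- function(p) {
    d <- ctm_transform(rotation = p[1:3], translation = p[4:6],
                       scale = exp(p[7:9]), center = center)
    ad <- transform_affine(d)
    list(A = af_init$A %*% ad$A,
         b = as.numeric(af_init$A %*% ad$b + af_init$b))
  }
  metric_at <- function(p, lev) {
    af <- full_affine(p)
    s <- 2^(lev - 1)
    h <- (s - 1) / 2
    bl <- (af$A %*% rep(h, 3) + af$b - h) / s
    fvec <- pyr_f[[lev]]
    res <- cpp_affine_resample(pyr_m[[lev]], dim_m[[lev]], dim_f[[lev]],
                               af$A, as.numeric(bl), FALSE, NA_real_)
    ok <- !is.na(res)
    if (mean(ok) < 0.25) return(-Inf)
    ncc(fvec[ok], res[ok])
  }

  p <- rep(0, 9)
  m0 <- metric_at(p, nlev)
  # capture stage: exhaustive integer translation search at the coarsest
  # level (the NCC basin of textured tissue is narrow, so a local
  # simplex started at identity would stall)
  if (is.finite(m0)) {
    s <- 2^(nlev - 1)
    rng <- seq(-capture_range, capture_range, by = s)
    best <- m0
    for (tz in rng) for (ty in rng) for (tx in rng) {
      q <- p
      q[4:6] <- c(tz, ty, tx)
      m <- metric_at(q, nlev)
      if (is.finite(m) && m > best) {
        best <- m
        p <- q
      }
    }
  }
  for (lev in rev(seq_len(nlev))) {
    fn <- function(par) -metric_at(par, lev)
    if (!is.finite(fn(p))) next  # no usable overlap at this level
    s <- 2^(lev - 1)
    # restart the simplex once per level: Nelder-Mead in 9 dimensions
    # routinely collapses before the scale axes are resolved
    for (round in 1:2) {
      psc <- c(rep(0.02, 3), rep(s, 3), rep(0.01, 3)) / round
      opt <- tryCatch(
        stats::optim(p, fn, method = "Nelder-Mead",
                     control = list(maxit = max_iter, reltol = 1e-4,
                                    parscale = psc)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value)) p <- opt$par
    }
  }
  # full-resolution polish: translation and scale of one axis form a
  # narrow diagonal valley in the NCC landscape (their displacement
  # fields are collinear over the dominant content), so each axis pair
  # is re-optimized jointly with a small 2D simplex, then the angles
  # with line searches
  fn1 <- function(par) -metric_at(par, 1L)
  if (is.finite(fn1(p))) {
    for (axis in 1:3) {
      idx <- c(3L + axis, 6L + axis)
      o <- tryCatch(
        stats::optim(p[idx], function(x) {
          q <- p; q[idx] <- x; fn1(q)
        }, method = "Nelder-Mead",
        control = list(maxit = 80, reltol = 1e-6,
                       parscale = c(1, 0.01))),
        error = function(e) NULL)
      if (!is.null(o) && is.finite(o$value) && o$value <= fn1(p))
        p[idx] <- o$par
    }
    for (j in 1:3) {
      o <- tryCatch(
        stats::optimize(function(x) {
          q <- p; q[j] <- x; fn1(q)
        }, lower = p[j] - 0.02, upper = p[j] + 0.02, tol = 2e-4),
        error = function(e) NULL)
      if (!is.null(o) && is.finite(o$objective) && o$objective <= fn1(p))
        p[j] <- o$minimum
    }
  }
  mfin <- metric_at(p, 1L)
  # failure = no usable overlap, or the metric never reached a meaningful
  # correlation (disjoint or unrelated content); never a silent identity
  failed <- !is.finite(mfin) || mfin < min_metric ||
    (is.finite(m0) && mfin < m0 - 1e-6)
  if (!is.finite(mfin)) mfin <- NA_real_

  af <- full_affine(p)
  # recover transform parameters from the composed affine: A = R S
  S <- sqrt(colSums(af$A^2))
  R <- af$A %*% diag(1 / S)
  tr <- ctm_transform(
    rotation = rotation_angles_from_matrix(R),
    translation = as.numeric(af$b + af$A %*% center - center),
    scale = S, center = center,
    final_metric = mfin,
    status = if (failed) "failed" else "converged")
  resampled <- apply_transform(moving, tr, out_dim = dim(fixed$data))
  list(transform = tr, metric = mfin, resampled = resampled)
}

#' XOR mismatch fraction between two binary volumes
#'
#' Percentage of voxels at which two equal-shape binary masks disagree
#' (the voxelwise symmetric difference) — the standard way to quantify
#' change between registered pre/post scans. Symmetric in its arguments.
#'
#' @param a,b logical 3D arrays of equal shape.
#' @return percent of voxels mismatched, in `[0, 100]`.
#' @export
xor_fraction <- function(a, b) {
  am <- as_vox_array(a) > 0
  bm <- as_vox_array(b) > 0
  if (!identical(dim(am), dim(bm))) stop("shapes differ")
  100 * mean(am != bm)
}

#' Correct an XOR mismatch for non-cell voxels
#'
#' The raw XOR mismatch between a registered pre/post pair includes
#' voxels that are airspace or vasculature rather than cells; once those
#' are identified (contrast makes them distinguishable), the mismatch
#' attributable to cells is the difference of the two percentages.
#'
#' @param mismatch_pct total XOR mismatch, percent of the VOI.
#' @param noncell_pct percent of the VOI identified as airspace plus
#'   vasculature; must not exceed `mismatch_pct`.
#' @return cell-attributable mismatch, percent.
#' @export
corrected_cell_difference <- function(mismatch_pct, noncell_pct) {
  if (any(noncell_pct < 0) || any(noncell_pct > mismatch_pct))
    stop("noncell_pct must be within [0, mismatch_pct]")
  mismatch_pct - noncell_pct
}
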