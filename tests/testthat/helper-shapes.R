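# Geometric fixtures built in code.

# Digitized ball of radius r (voxels), centered, with padding.
make_ball <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  idx <- seq_len(n) - c0
  a <- array(FALSE, c(n, n, n))
  for (z in seq_len(n))
    a[z, , ] <- outer(idx, idx, function(y, x) idx[z]^2 + y^2 + x^2 <= r^2)
  a
}

# Solid axis-aligned ellipsoid with semi-axes (az, ay, ax) voxels.
make_ellipsoid <- function(az, ay, ax, pad = 3) {
  nz <- 2 * (az + pad) + 1
  ny <- 2 * (ay + pad) + 1
  nx <- 2 * (ax + pad) + 1
  zi <- seq_len(nz) - (az + pad + 1)
  yi <- seq_len(ny) - (ay + pad + 1)
  xi <- seq_len(nx) - (ax + pad + 1)
  a <- array(FALSE, c(nz, ny, nx))
  for (z in seq_len(nz))
    a[z, , ] <- outer(yi, xi, function(y, x)
      (zi[z] / az)^2 + (y / ay)^2 + (x / ax)^2 <= 1)
  a
}

# Two balls of radius r with centers `sep` voxels apart along y, merged.
make_two_balls <- function(r = 10, sep = 16, pad = 6) {
  ny <- sep + 2 * (r + pad)
  n <- 2 * (r + pad)
  cz <- n / 2
  cy1 <- r + pad
  cy2 <- cy1 + sep
  a <- array(FALSE, c(n, ny, n))
  yi <- seq_len(ny)
  xi <- seq_len(n)
  for (z in seq_len(n)) {
    dz2 <- (z - cz)^2
    a[z, , ] <- outer(yi, xi, function(y, x)
      dz2 + (y - cy1)^2 + (x - cz)^2 <= r^2 |
        dz2 + (y - cy2)^2 + (x - cz)^2 <= r^2)
  }
  list(mask = a, centers_y = c(cy1, cy2), mid_y = (cy1 + cy2) / 2)
}

# Cached phantoms: generating one takes seconds, several tests share them.
phantom_cache <- new.env()

cached_phantom <- function(key, spec) {
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- generate_tissue(spec)
  phantom_cache[[key]]
}

enhanced_phantom_96 <- function() {
  cached_phantom("enh96", phantom_spec(shape = c(96, 96, 96),
                                       contrast_mode = TRUE,
                                       random_seed = 7))
}
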