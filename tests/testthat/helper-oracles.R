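# Independent brute-force oracles. These deliberately avoid the package's
# compiled code paths: plain-R loops and array arithmetic only.

# Direct 3x3x3 Sobel convolution at interior voxels (replicate-border-free
# region) of a small volume. Returns the magnitude array with NA at the
# border.
oracle_sobel <- function(vol) {
  d <- dim(vol)
  smooth <- c(1, 2, 1)
  deriv <- c(-1, 0, 1)
  out <- array(NA_real_, d)
  for (z in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (x in 2:(d[3] - 1)) {
    g <- c(0, 0, 0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      v <- vol[z + dz, y + dy, x + dx]
      g[1] <- g[1] + v * deriv[dz + 2] * smooth[dy + 2] * smooth[dx + 2]
      g[2] <- g[2] + v * smooth[dz + 2] * deriv[dy + 2] * smooth[dx + 2]
      g[3] <- g[3] + v * smooth[dz + 2] * smooth[dy + 2] * deriv[dx + 2]
    }
    out[z, y, x] <- sqrt(sum(g^2))
  }
  out
}

# 26-connected flood fill component sizes by repeated frontier expansion.
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    frontier <- v
    lab[v] <- nxt
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      new <- integer(0)
      for (k in seq_len(nrow(nb))) {
        cz <- co[, 1] + nb$dz[k]
        cy <- co[, 2] + nb$dy[k]
        cx <- co[, 3] + nb$dx[k]
        okv <- cz >= 1 & cz <= d[1] & cy >= 1 & cy <= d[2] &
          cx >= 1 & cx <= d[3]
        if (!any(okv)) next
        ii <- cz[okv] + d[1] * (cy[okv] - 1) + d[1] * d[2] * (cx[okv] - 1)
        ii <- ii[mask[ii] & lab[ii] == 0L]
        lab[ii] <- nxt
        new <- c(new, ii)
      }
      frontier <- unique(new)
    }
  }
  lab
}

# Two-seed region growing on the exact Euclidean distance-to-seed-center
# landscape: each foreground voxel goes to the nearer of the two centers.
# The equidistant plane is the expected watershed split for two balls.
oracle_two_seed_split <- function(mask, c1, c2) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  co <- arrayInd(idx, d)
  d1 <- (co[, 1] - c1[1])^2 + (co[, 2] - c1[2])^2 + (co[, 3] - c1[3])^2
  d2 <- (co[, 1] - c2[1])^2 + (co[, 2] - c2[2])^2 + (co[, 3] - c2[3])^2
  lab[idx] <- ifelse(d1 <= d2, 1L, 2L)
  lab
}

# Labels touching a face, found by scanning all six faces directly.
oracle_border_labels <- function(labels) {
  d <- dim(labels)
  face <- c(labels[1, , ], labels[d[1], , ], labels[, 1, ],
            labels[, d[2], ], labels[, , 1], labels[, , d[3]])
  sort(unique(face[face > 0L]))
}

# Pooled-variance two-sample t statistic and p value, evaluated directly
# from the textbook formula.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
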