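#' 3D greyscale volume
#'
#' Container for a 3D scalar voxel grid with an isotropic voxel size.
#' The array is indexed `[z, y, x]` (slice, row, column; 1-based as usual
#' in R) so that TIFF pages map onto the first index. All ctmorph
#' functions use this convention.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @param bit_depth 8 or 16 (12-bit acquisitions are stored in 16-bit
#'   containers). Determines the valid intensity range `[0, 2^bit_depth-1]`.
#' @return an object of class `ctm_volume`.
#' @export
ctm_volume <- function(data, voxel_size, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometers)")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside the bit-depth range [0, ", 2^bit_depth - 1, "]")
  structure(list(data = data, voxel_size = voxel_size,
                 bit_depth = bit_depth),
            class = "ctm_volume")
}

#' 3D label volume
#'
#' Integer voxel grid where 0 is background and each positive integer k
#' identifies object k. Shares the `[z, y, x]` indexing convention of
#' [ctm_volume()].
#'
#' @param data 3D integer array.
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @return an object of class `ctm_labels`.
#' @export
ctm_labels <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometers)")
  structure(list(data = data, voxel_size = voxel_size),
            class = "ctm_labels")
}

#' @export
print.ctm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ctm_volume> %d x %d x %d voxels (z,y,x), %g um/voxel, %d-bit\n",
              d[1], d[2], d[3], x$voxel_size, x$bit_depth))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ctm_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ctm_labels> %d x %d x %d voxels (z,y,x), %g um/voxel, %d labels\n",
              d[1], d[2], d[3], x$voxel_size, max(x$data)))
  invisible(x)
}

#' @export
dim.ctm_volume <- function(x) dim(x$data)

#' @export
dim.ctm_labels <- function(x) dim(x$data)

# Internal: pull the bare array out of a volume/labels/array argument.
as_vox_array <- function(x) {
  if (inherits(x, "ctm_volume") || inherits(x, "ctm_labels")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a ctm_volume, ctm_labels or 3D array")
}

# Internal: voxel size of a volume-like object, with fallback.
vox_size_of <- function(x, voxel_size = NULL) {
  if (!is.null(voxel_size)) return(voxel_size)
  if (inherits(x, "ctm_volume") || inherits(x, "ctm_labels"))
    return(x$voxel_size)
  stop("voxel size not available; pass `voxel_size`")
}
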