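#' Read a volume from a multi-page TIFF or a directory of slice TIFFs
#'
#' The voxel size (micrometers) is taken from a JSON sidecar written by
#' [write_volume()] (`<stem>.json` next to the file, `volume.json` inside
#' a slice directory) or from the `voxel_size` argument. There is no
#' silent default: a missing voxel size is an error.
#'
#' @param path a multi-page TIFF file or a directory of per-slice TIFFs
#'   (stacked in lexicographic filename order).
#' @param voxel_size optional voxel size in micrometers, overriding the
#'   sidecar.
#' @return a [ctm_volume()].
#' @seealso [write_volume()], [rescale_to_8bit()]
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF slices in directory: ", path)
    pages <- lapply(files, read_tiff_stack)
    shp <- vapply(pages, function(p) dim(p$data)[2:3], integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
      stop("slice TIFFs have differing shapes")
    nz <- sum(vapply(pages, function(p) dim(p$data)[1], integer(1)))
    arr <- array(0, dim = c(nz, shp[1, 1], shp[2, 1]))
    z <- 1L
    for (p in pages) {
      k <- dim(p$data)[1]
      arr[z:(z + k - 1L), , ] <- p$data
      z <- z + k
    }
    bits <- max(vapply(pages, function(p) p$bit_depth, integer(1)))
    sidecar <- file.path(path, "volume.json")
  } else {
    stack <- read_tiff_stack(path)
    arr <- stack$data
    bits <- stack$bit_depth
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  }
  if (is.null(voxel_size)) {
    if (!file.exists(sidecar))
      stop("voxel size unknown: no sidecar at ", sidecar,
           " and no `voxel_size` given")
    meta <- jsonlite::read_json(sidecar)
    voxel_size <- meta$voxel_size_um
    if (is.null(voxel_size)) stop("sidecar lacks voxel_size_um: ", sidecar)
  }
  ctm_volume(arr, voxel_size = as.numeric(voxel_size), bit_depth = bits)
}

#' Write a volume as a multi-page TIFF (plus JSON sidecar)
#'
#' Writes uncompressed greyscale baseline TIFF. If `path` is an existing
#' directory (or ends in `/`), one TIFF per z-slice is written instead.
#' A JSON sidecar records voxel size and bit depth so that
#' [read_volume()] can round-trip the volume bit-identically.
#'
#' @param volume a [ctm_volume()] or [ctm_labels()] (labels are stored as
#'   16-bit greyscale).
#' @param path output file or directory.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "ctm_labels")) {
    if (max(volume$data) > 65535)
      stop("more than 65535 labels cannot be stored in 16-bit TIFF")
    arr <- volume$data
    bits <- 16L
    vs <- volume$voxel_size
  } else {
    arr <- as_vox_array(volume)
    bits <- volume$bit_depth
    vs <- volume$voxel_size
  }
  meta <- list(voxel_size_um = vs, bit_depth = bits,
               shape_zyx = dim(arr), writer = "ctmorph")
  as_dir <- dir.exists(path) || grepl("/$", path)
  if (as_dir) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    nz <- dim(arr)[1]
    for (z in seq_len(nz)) {
      f <- file.path(path, sprintf("slice_%05d.tif", z))
      write_tiff_stack(arr[z, , , drop = FALSE], f, bits)
    }
    jsonlite::write_json(meta, file.path(path, "volume.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    write_tiff_stack(arr, path, bits)
    jsonlite::write_json(meta,
                         paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Linearly rescale a >8-bit volume to 8 bits
#'
#' Maps the observed intensity range `[min, max]` linearly onto
#' `[0, 255]`, rounding half away from zero. Micro-CT reconstructions are
#' routinely downscaled this way to cut memory and processing cost; the
#' map is monotone so ordering of intensities is preserved. A constant
#' volume cannot be rescaled meaningfully: it yields all zeros with a
#' warning.
#'
#' @param volume a [ctm_volume()] with `bit_depth > 8`.
#' @return an 8-bit [ctm_volume()].
#' @export
rescale_to_8bit <- function(volume) {
  stopifnot(inherits(volume, "ctm_volume"))
  if (volume$bit_depth <= 8L)
    stop("volume is already 8-bit")
  lo <- min(volume$data)
  hi <- max(volume$data)
  if (hi == lo) {
    warning("constant volume: rescale produces all zeros")
    out <- array(0, dim = dim(volume$data))
  } else {
    x <- (volume$data - lo) / (hi - lo) * 255
    out <- floor(x + 0.5)  # round half away from zero (values are >= 0)
  }
  ctm_volume(out, voxel_size = volume$voxel_size, bit_depth = 8L)
}

# Canonical cell-table column order; units are part of the header names.
cell_table_columns <- c(
  "label_id", "volume_um3", "equivalent_diameter_um", "surface_area_um2",
  "sphericity", "anisotropy", "centroid_z_um", "centroid_y_um",
  "centroid_x_um", "touches_border", "structure_class")

#' Write / read a per-cell morphometry table (CSV)
#'
#' One row per labeled object with the full set of morphometry fields in
#' a stable column order; units are embedded in the column names. The
#' round trip through [read_cell_table()] is lossless to full double
#' precision.
#'
#' @param cells data frame of cell records as produced by
#'   [measure_labels()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  if (!nrow(cells)) {
    cells <- as.data.frame(setNames(
      rep(list(logical(0)), length(cell_table_columns)), cell_table_columns))
  }
  missing <- setdiff(cell_table_columns, names(cells))
  if (length(missing))
    stop("cell table lacks columns: ", paste(missing, collapse = ", "))
  write.csv(format(cells[cell_table_columns], digits = 17, trim = TRUE,
                   scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$label_id <- as.integer(df$label_id)
    df$touches_border <- as.logical(df$touches_border)
    num <- setdiff(cell_table_columns,
                   c("label_id", "touches_border", "structure_class"))
    for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}
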