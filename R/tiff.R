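# Minimal baseline TIFF codec: little-endian, greyscale, uncompressed,
# 8- or 16-bit, multi-page. None of the R imaging packages available in
# this stack read stacked TIFFs, so the dialect needed for micro-CT
# exports is implemented here directly and cross-validated against an
# independent reader in the test suite. Only the baseline subset is
# supported; compressed or tiled files are rejected loudly.

tiff_u16 <- function(r, pos) {
  as.integer(r[pos]) + 256L * as.integer(r[pos + 1L])
}

tiff_u32 <- function(r, pos) {
  as.numeric(r[pos]) + 256 * as.numeric(r[pos + 1L]) +
    65536 * as.numeric(r[pos + 2L]) + 16777216 * as.numeric(r[pos + 3L])
}

tiff_pack_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(rbind(x %% 256L, x %/% 256L)))
}

tiff_pack_u32 <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(c(rbind(b0, b1, b2, b3)))
}

# One IFD entry: tag, type (3 = SHORT, 4 = LONG), count 1, inline value.
tiff_entry <- function(tag, type, value) {
  val <- if (type == 3L) c(tiff_pack_u16(value), as.raw(c(0, 0)))
         else tiff_pack_u32(value)
  c(tiff_pack_u16(tag), tiff_pack_u16(type), tiff_pack_u32(1L), val)
}

# Write a 3D array (z = page, y = row, x = column) as a multi-page
# greyscale TIFF. `bits` is 8 or 16.
write_tiff_stack <- function(arr, path, bits) {
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  bpp <- bits / 8L
  strip_bytes <- nx * ny * bpp
  n_entries <- 9L
  ifd_bytes <- 2L + 12L * n_entries + 4L
  data_off <- 8 + (0:(nz - 1)) * strip_bytes
  ifd_off <- 8 + nz * strip_bytes + (0:(nz - 1)) * ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49, 0x2a, 0x00)), tiff_pack_u32(ifd_off[1])),
           con)
  for (z in seq_len(nz)) {
    slice <- arr[z, , , drop = TRUE]
    if (ny == 1L || nx == 1L) slice <- matrix(slice, ny, nx)
    px <- as.vector(t(slice))  # row-major: x fastest
    px <- as.integer(round(px))
    if (bits == 8L) {
      writeBin(as.raw(px), con)
    } else {
      writeBin(tiff_pack_u16(px %% 65536L), con)
    }
  }
  for (z in seq_len(nz)) {
    entries <- c(
      tiff_entry(256L, 4L, nx),           # ImageWidth
      tiff_entry(257L, 4L, ny),           # ImageLength
      tiff_entry(258L, 3L, bits),         # BitsPerSample
      tiff_entry(259L, 3L, 1L),           # Compression: none
      tiff_entry(262L, 3L, 1L),           # Photometric: BlackIsZero
      tiff_entry(273L, 4L, data_off[z]),  # StripOffsets
      tiff_entry(277L, 3L, 1L),           # SamplesPerPixel
      tiff_entry(278L, 4L, ny),           # RowsPerStrip
      tiff_entry(279L, 4L, strip_bytes)   # StripByteCounts
    )
    nxt <- if (z < nz) ifd_off[z + 1] else 0
    writeBin(c(tiff_pack_u16(n_entries), entries, tiff_pack_u32(nxt)), con)
  }
  invisible(path)
}

# Read tag values (possibly stored out of line) from a raw buffer.
# Types other than BYTE/SHORT/LONG (e.g. ASCII descriptions, RATIONAL
# resolutions written by other software) are skipped by the caller.
tiff_tag_values <- function(r, type, count, valfield_pos) {
  size <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NULL)
  if (is.null(size)) return(NULL)
  total <- size * count
  pos <- if (total <= 4L) valfield_pos else tiff_u32(r, valfield_pos) + 1
  vapply(seq_len(count), function(i) {
    p <- pos + (i - 1L) * size
    if (size == 1L) as.numeric(r[p])
    else if (size == 2L) as.numeric(tiff_u16(r, p))
    else tiff_u32(r, p)
  }, numeric(1))
}

# Read a (multi-page) greyscale TIFF into a 3D array plus bit depth.
read_tiff_stack <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 8) stop("not a TIFF file: ", path)
  if (!(r[1] == 0x49 && r[2] == 0x49))
    stop("only little-endian TIFF is supported: ", path)
  if (tiff_u16(r, 3) != 42L) stop("not a TIFF file: ", path)
  ifd <- tiff_u32(r, 5)
  slices <- list()
  bits_seen <- NULL
  while (ifd != 0) {
    p <- ifd + 1  # raw vector is 1-based
    n_entries <- tiff_u16(r, p)
    tags <- list()
    for (e in seq_len(n_entries)) {
      ep <- p + 2 + (e - 1) * 12
      tag <- tiff_u16(r, ep)
      type <- tiff_u16(r, ep + 2)
      count <- tiff_u32(r, ep + 4)
      vals <- tiff_tag_values(r, type, count, ep + 8)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", tag)
        default
      } else v
    }
    nx <- need(256); ny <- need(257)
    bits <- need(258, 8)
    if (!bits %in% c(8, 16)) stop("unsupported bit depth: ", bits)
    if (need(259, 1) != 1) stop("compressed TIFF not supported: ", path)
    if (need(277, 1) != 1) stop("only single-sample greyscale supported")
    offs <- need(273)
    counts <- need(279, nx * ny * bits / 8)
    px <- numeric(0)
    for (s in seq_along(offs)) {
      seg <- r[(offs[s] + 1):(offs[s] + counts[s])]
      if (bits == 8) {
        px <- c(px, as.numeric(seg))
      } else {
        lo <- as.numeric(seg[seq(1, length(seg), 2)])
        hi <- as.numeric(seg[seq(2, length(seg), 2)])
        px <- c(px, lo + 256 * hi)
      }
    }
    if (length(px) != nx * ny)
      stop("TIFF strip data does not match page dimensions")
    slices[[length(slices) + 1L]] <- matrix(px, nrow = ny, byrow = TRUE)
    bits_seen <- c(bits_seen, bits)
    ifd <- tiff_u32(r, p + 2 + n_entries * 12)
  }
  if (!length(slices)) stop("TIFF contains no pages: ", path)
  shp <- vapply(slices, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("TIFF pages have differing shapes")
  nz <- length(slices)
  arr <- array(0, dim = c(nz, shp[1, 1], shp[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]
  list(data = arr, bit_depth = as.integer(max(bits_seen)))
}
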