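test_that("volume containers validate their invariants", {
  expect_error(ctm_volume(matrix(0, 2, 2), 2.5), "3D")
  expect_error(ctm_volume(array(0, c(4, 4, 4)), -1), "positive")
  expect_error(ctm_volume(array(300, c(4, 4, 4)), 2.5, 8L), "range")
  expect_error(ctm_labels(array(-1L, c(4, 4, 4)), 2.5), "non-negative")
})

test_that("multi-page TIFF roundtrip is bit-identical (8 and 16 bit)", {
  for (bits in c(8L, 16L)) {
    set.seed(bits)
    arr <- array(sample.int(2^bits, 64^3, replace = TRUE) - 1L,
                 c(64, 64, 64))
    vol <- ctm_volume(arr, voxel_size = 2.75, bit_depth = bits)
    path <- tempfile(fileext = ".tif")
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$data, vol$data + 0)  # numeric comparison
    expect_equal(back$voxel_size, 2.75)
    expect_equal(back$bit_depth, bits)
    unlink(c(path, sub("\\.tif$", ".json", path)))
  }
})

test_that("slice directory and multi-page file load identically", {
  set.seed(1)
  arr <- array(sample.int(256, 24^3, replace = TRUE) - 1L, c(24, 24, 24))
  vol <- ctm_volume(arr, 2.5, 8L)
  f <- tempfile(fileext = ".tif")
  d <- tempfile()
  dir.create(d)
  write_volume(vol, f)
  write_volume(vol, d)
  a <- read_volume(f)
  b <- read_volume(d)
  expect_identical(a$data, b$data)
  unlink(c(f, sub("\\.tif$", ".json", f)))
  unlink(d, recursive = TRUE)
})

test_that("mixed slice shapes and missing voxel size are errors", {
  d <- tempfile()
  dir.create(d)
  ctmorph:::write_tiff_stack(array(0, c(1, 8, 8)),
                             file.path(d, "slice_00001.tif"), 8L)
  ctmorph:::write_tiff_stack(array(0, c(1, 9, 8)),
                             file.path(d, "slice_00002.tif"), 8L)
  expect_error(read_volume(d, voxel_size = 2.5), "differing shapes")
  unlink(d, recursive = TRUE)

  f <- tempfile(fileext = ".tif")
  ctmorph:::write_tiff_stack(array(7, c(2, 8, 8)), f, 8L)
  expect_error(read_volume(f), "voxel size")
  expect_silent(v <- read_volume(f, voxel_size = 3))
  expect_equal(v$voxel_size, 3)
  unlink(f)
})

test_that("the TIFF dialect agrees with an independent reader/writer", {
  # tifffile (Python) as the external oracle, both directions
  py <- Sys.which("python")
  set.seed(9)
  arr <- array(sample.int(4096, 16^3, replace = TRUE) - 1L, c(16, 16, 16))
  vol <- ctm_volume(arr, 2.5, 16L)
  ours <- tempfile(fileext = ".tif")
  theirs <- tempfile(fileext = ".tif")
  npy <- tempfile(fileext = ".txt")
  write_volume(vol, ours)
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(%s)\n",
    "np.savetxt(%s, a.reshape(a.shape[0], -1), fmt='%%d')\n",
    "tifffile.imwrite(%s, a)\n"),
    deparse(ours), deparse(npy), deparse(theirs))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  m <- as.matrix(read.table(npy))  # one z-slice per row, row-major (y, x)
  their_arr <- array(NA_real_, dim(arr))
  for (z in 1:16) their_arr[z, , ] <- matrix(m[z, ], 16, 16, byrow = TRUE)
  expect_equal(their_arr, arr + 0)
  back <- read_volume(theirs, voxel_size = 2.5)
  expect_identical(back$data, arr + 0)
  unlink(c(ours, theirs, npy, sf, sub("\\.tif$", ".json", ours)))
})

test_that("rescale_to_8bit maps linearly with round-half-away-from-zero", {
  v <- ctm_volume(array(c(0, 4095, rep(0, 25)), c(3, 3, 3)), 2.5, 16L)
  out <- rescale_to_8bit(v)
  expect_equal(range(out$data), c(0, 255))
  v2 <- ctm_volume(array(c(0, 2047, 4095, rep(0, 24)), c(3, 3, 3)), 2.5,
                   16L)
  out2 <- rescale_to_8bit(v2)
  # 2047/4095*255 = 127.47 -> 127 under round-half-away-from-zero
  expect_equal(sort(unique(as.numeric(out2$data))), c(0, 127, 255))
  # monotone map on random data
  set.seed(4)
  r <- array(sample.int(4096, 5^3, replace = TRUE) - 1, c(5, 5, 5))
  vr <- rescale_to_8bit(ctm_volume(r, 1, 16L))
  o <- order(as.numeric(r))
  expect_true(all(diff(as.numeric(vr$data)[o]) >= 0))
  expect_warning(
    const <- rescale_to_8bit(ctm_volume(array(7, c(3, 3, 3)), 1, 16L)),
    "constant")
  expect_true(all(const$data == 0))
  expect_error(rescale_to_8bit(ctm_volume(array(1, c(3, 3, 3)), 1, 8L)),
               "already")
})

test_that("cell tables roundtrip losslessly with stable columns", {
  lab <- ctm_labels(array(c(rep(1L, 10), rep(0L, 17)), c(3, 3, 3)), 2.5)
  cells <- measure_labels(lab)
  f <- tempfile(fileext = ".csv")
  write_cell_table(cells, f)
  back <- read_cell_table(f)
  expect_equal(names(back), ctmorph:::cell_table_columns)
  expect_equal(back$volume_um3, cells$volume_um3, tolerance = 1e-6)
  expect_equal(back$touches_border, cells$touches_border)
  # empty table -> header-only file
  f2 <- tempfile(fileext = ".csv")
  write_cell_table(cells[0, ], f2)
  expect_equal(nrow(read_cell_table(f2)), 0L)
  expect_equal(names(read_cell_table(f2)), ctmorph:::cell_table_columns)
  unlink(c(f, f2))
})
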