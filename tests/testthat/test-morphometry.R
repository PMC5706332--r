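test_that("extract_voi copies exact sub-grids and enforces the minimum", {
  set.seed(5)
  arr <- array(sample.int(256, 96^3, replace = TRUE) - 1L, c(96, 96, 96))
  vol <- ctm_volume(arr, voxel_size = 25, bit_depth = 8L)  # 2.4 mm cube
  # 2400 um at 25 um voxels -> 96 voxels per edge (full volume, identity)
  full <- extract_voi(vol, voi_spec(c(1, 1, 1), c(2400, 2400, 2400)))
  expect_identical(full$data, arr)
  # interior VOI is an exact sub-grid copy with metadata preserved
  sub <- extract_voi(vol, voi_spec(c(10, 20, 30), c(1200, 1200, 1200)),
                     enforce_minimum = FALSE)
  expect_identical(sub$data, arr[10:57, 20:67, 30:77])
  expect_equal(sub$voxel_size, 25)
  # 1 mm^3 request is below the 1.3 mm^3 representative minimum
  expect_error(extract_voi(vol, voi_spec(c(1, 1, 1), rep(1000, 3))),
               "1.3 mm")
  # out-of-bounds VOI
  expect_error(extract_voi(vol, voi_spec(c(90, 1, 1), rep(2400, 3))),
               "fit")
})

test_that("equivalent diameter inverts the sphere volume formula", {
  expect_equal(equivalent_diameter(pi / 6 * 100^3), 100)
  ball <- make_ball(50, pad = 2)
  expect_lt(abs(equivalent_diameter(sum(ball)) - 100) / 100, 0.02)
  expect_error(equivalent_diameter(0), "positive")
})

test_that("sphericity follows the Wadell definition", {
  v <- pi / 6 * 80^3
  a <- pi * 80^2
  expect_equal(sphericity(v, a), 1)
  expect_equal(sphericity(20^3, 6 * 20^2), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_error(sphericity(-1, 10), "positive")
})

test_that("surface area is accurate for smooth and polyhedral bodies", {
  ball <- make_ball(20)
  expect_lt(abs(surface_area(ball) - 4 * pi * 400) / (4 * pi * 400), 0.03)
  cube <- array(FALSE, c(30, 30, 30))
  cube[6:25, 6:25, 6:25] <- TRUE
  expect_lt(abs(surface_area(cube) - 2400) / 2400, 0.05)
  one <- array(TRUE, c(1, 1, 1))
  expect_gt(surface_area(one), 0)
  expect_true(is.finite(surface_area(one)))
  # the triangulated-isosurface method agrees on the ball
  expect_lt(abs(surface_area(ball, method = "mesh") - 4 * pi * 400) /
              (4 * pi * 400), 0.03)
  expect_gt(surface_area(one, method = "mesh"), 0)
  expect_error(surface_area(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("anisotropy matches moment eigenvalue ratios", {
  expect_lte(anisotropy(make_ball(15)), 0.02)
  ell <- make_ellipsoid(20, 10, 10)
  expect_lt(abs(anisotropy(ell) - 0.75), 0.02)
  one <- array(c(TRUE), c(1, 1, 1))
  expect_equal(anisotropy(one), 0)
  expect_error(anisotropy(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("measure_labels conserves volume exactly and flags borders", {
  a <- array(0L, c(14, 14, 14))
  a[3:12, 3:12, 3:12] <- 1L  # 10^3 cube at 2.5 um
  cells <- measure_labels(ctm_labels(a, 2.5))
  expect_equal(cells$volume_um3, 1000 * 2.5^3)  # 15625 exactly
  expect_false(cells$touches_border)
  # volume conservation over many labels
  ph <- enhanced_phantom_96()
  tl <- ph$truth_labels
  cells <- measure_labels(tl)
  expect_equal(sum(cells$volume_um3),
               sum(tl$data > 0) * tl$voxel_size^3)
  # diameters of truth cells within 10% median of voxel-count diameters
  tv <- tabulate(tl$data)[cells$label_id] * tl$voxel_size^3
  expect_equal(cells$volume_um3, tv)
  # empty labels -> empty table
  expect_equal(nrow(measure_labels(
    ctm_labels(array(0L, c(8, 8, 8)), 1))), 0L)
})

test_that("morphometry is scale-equivariant", {
  a <- array(0L, c(16, 16, 16))
  a[4:12, 5:11, 6:12] <- 1L
  c1 <- measure_labels(ctm_labels(a, 1))
  c2 <- measure_labels(ctm_labels(a, 2))
  expect_equal(c2$volume_um3 / c1$volume_um3, 8)
  expect_equal(c2$surface_area_um2 / c1$surface_area_um2, 4)
  expect_equal(c2$equivalent_diameter_um / c1$equivalent_diameter_um, 2)
  expect_equal(c2$sphericity, c1$sphericity, tolerance = 1e-9)
  expect_equal(c2$anisotropy, c1$anisotropy, tolerance = 1e-9)
})

test_that("summarize_voi computes percentages and handles empties", {
  ph <- enhanced_phantom_96()
  cells <- measure_labels(ph$truth_labels)
  voi_vol <- prod(dim(ph$truth_labels$data)) * 2.5^3
  s <- summarize_voi(cells, NULL, voi_vol)
  truth_pct <- 100 * sum(ph$truth_labels$data > 0) /
    prod(dim(ph$truth_labels$data))
  expect_lt(abs(s$filtered_cell_volume_pct - truth_pct), 1)
  expect_equal(s$cell_count, nrow(cells))
  empty <- summarize_voi(cells[0, ], NULL, voi_vol)
  expect_equal(empty$filtered_cell_volume_pct, 0)
  expect_equal(empty$cell_count, 0L)
  expect_error(summarize_voi(cells, NULL, 0), "positive")
})

test_that("replicate aggregation reports SEM = SD/sqrt(n)", {
  mk <- function(p) structure(list(
    voi_volume_um3 = 1, borderkilled_cell_volume_pct = p,
    filtered_cell_volume_pct = p, structures_volume_pct = 0,
    cell_count = round(p * 10), mean_equivalent_diameter_um = 100,
    mean_anisotropy = 0.5), class = "voi_summary")
  reps <- lapply(c(20, 22, 24, 26), mk)
  agg <- summarize_replicates(reps)
  row <- agg[agg$field == "filtered_cell_volume_pct", ]
  expect_equal(row$mean, 23)
  expect_equal(row$sem, sd(c(20, 22, 24, 26)) / 2)
  single <- summarize_replicates(reps[1])
  expect_true(all(is.na(single$sem)))
})

test_that("percent_increase reproduces the published cell-count rows", {
  expect_equal(percent_increase(951.25, 1312.75), 38.00)
  expect_equal(percent_increase(1060.25, 2540.25), 139.59)
  expect_equal(percent_increase(114.25, 162.25), 42.01)
  expect_equal(percent_increase(5, 5), 0)
  expect_error(percent_increase(0, 10), "positive")
})
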