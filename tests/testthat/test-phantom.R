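test_that("phantom_spec validates its invariants", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(shape = c(16, 64, 64)), ">= 32")
  expect_error(phantom_spec(target_porosity = 0.6), "0, 0.5")
  expect_error(phantom_spec(wall_thickness = 0), "wall_thickness")
  expect_error(phantom_spec(intensity_levels = list(air = 300, cell = 120,
    contrast_boundary = 230, flooded_airspace = 200, vasculature = 240,
    stone_cell = 210)), "0, 255")
  expect_error(phantom_spec(contrast_mode = TRUE,
    intensity_levels = list(air = 5, cell = 240, contrast_boundary = 230,
      flooded_airspace = 200, vasculature = 240, stone_cell = 210)),
    "contrast_boundary > cell > air")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("presets carry the three stated porosities", {
  expect_equal(phantom_preset("apple")$target_porosity, 0.20)
  expect_equal(phantom_preset("pear")$target_porosity, 0.10)
  expect_equal(phantom_preset("tomato")$target_porosity, 0.05)
})

test_that("generated porosity hits the target within one percentage point", {
  for (p in c(0.05, 0.10, 0.20)) {
    ph <- generate_tissue(phantom_spec(shape = c(64, 64, 64),
                                       target_porosity = p,
                                       random_seed = 11))
    expect_lt(abs(ph$achieved_porosity - p), 0.01)
    expect_equal(sum(ph$truth_air) / prod(dim(ph$truth_air)),
                 ph$achieved_porosity)
  }
})

test_that("zero target porosity yields no air voxels", {
  ph <- generate_tissue(phantom_spec(shape = c(48, 48, 48),
                                     target_porosity = 0, random_seed = 2))
  expect_false(any(ph$truth_air))
})

test_that("identical spec and seed reproduce the phantom bit-identically", {
  spec <- phantom_spec(shape = c(48, 48, 48), contrast_mode = TRUE,
                       random_seed = 13)
  a <- generate_tissue(spec)
  b <- generate_tissue(spec)
  expect_identical(a$greyscale$data, b$greyscale$data)
  expect_identical(a$truth_labels$data, b$truth_labels$data)
  expect_identical(a$truth_air, b$truth_air)
})

test_that("truth masks are pairwise disjoint and labels cover seeds", {
  ph <- enhanced_phantom_96()
  expect_false(any(ph$truth_air & ph$truth_labels$data > 0))
  expect_false(any(ph$truth_structures$data > 0 &
                     ph$truth_labels$data > 0))
  expect_gt(max(ph$truth_labels$data), 2)
})

test_that("realized cell diameters cluster near the requested diameter", {
  ph <- enhanced_phantom_96()
  tl <- ph$truth_labels$data
  vols <- tabulate(tl) * ph$spec$voxel_size^3
  interior <- !(seq_along(vols) %in% oracle_border_labels(tl))
  d_eq <- equivalent_diameter(vols[interior & vols > 0])
  expect_lt(abs(median(d_eq) - ph$spec$mean_cell_diameter) /
              ph$spec$mean_cell_diameter, 0.25)
})

test_that("additive imaging noise matches its contract", {
  flat <- ctm_volume(array(120, c(50, 50, 50)), 2.5, 8L)
  expect_identical(add_imaging_noise(flat, 0)$data, flat$data)
  noisy <- add_imaging_noise(flat, 8, seed = 5)
  expect_lt(abs(sd(noisy$data) - 8) / 8, 0.10)
  expect_lt(abs(mean(noisy$data) - 120), 0.5)
  expect_identical(noisy$data, add_imaging_noise(flat, 8, seed = 5)$data)
  expect_false(identical(noisy$data,
                         add_imaging_noise(flat, 8, seed = 6)$data))
  expect_error(add_imaging_noise(flat, -2), "noise_sd")
})

test_that("contrast-mode histogram is classifiable within 2% of truth", {
  ph <- enhanced_phantom_96()
  cl <- classify_intensities(ph$greyscale, 3L)
  expect_lt(mean(cl$data != ph$truth_classes), 0.02)
})

test_that("inclusions are painted, disjoint, and sized as stated", {
  spec <- phantom_spec(shape = c(128, 96, 96), contrast_mode = TRUE,
                      noise_sd = 0, random_seed = 21)
  ph <- generate_tissue(spec)
  set.seed(31)
  ph <- add_inclusions(ph, vessel_radius = 25, cluster_diameter = 100,
                       n_clusters = 3)
  expect_identical(unname(ph$structure_classes),
                   c("vasculature", rep("brachysclereid", 3)))
  # tube voxel count close to the analytic cylinder volume
  rv <- 25 / spec$voxel_size
  tube <- sum(ph$truth_structures$data == 1L)
  expect_lt(abs(tube - pi * rv^2 * 128) / (pi * rv^2 * 128), 0.10)
  # tube is one elongated component; clusters are 3 separate components
  d <- dim(ph$truth_structures$data)
  for (k in 2:4) {
    comp <- oracle_components(ph$truth_structures$data == k)
    expect_equal(max(comp), 1L)
  }
  expect_error(
    add_inclusions(generate_tissue(
      phantom_spec(shape = c(48, 48, 48), contrast_mode = TRUE,
                   random_seed = 1)),
      vessel_radius = 100, cluster_diameter = 0),
    "fit")
})

test_that("inclusions require contrast mode", {
  ph <- generate_tissue(phantom_spec(shape = c(48, 48, 48),
                                     random_seed = 3))
  expect_error(add_inclusions(ph, 10, 0), "contrast")
})
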