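test_that("transform inversion composes to the identity", {
  tr <- ctm_transform(rotation = c(0.1, -0.2, 0.05),
                      translation = c(3, -2, 1),
                      scale = c(1.05, 0.97, 1.01), center = c(24, 24, 24))
  af <- ctmorph:::transform_affine(tr)
  inv <- invert_transform(tr)
  expect_equal(inv$A %*% af$A, diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(inv$A %*% af$b + inv$b), rep(0, 3),
               tolerance = 1e-10)
})

test_that("principal-axes pre-alignment recovers pose and degeneracy", {
  ell <- make_ellipsoid(16, 8, 6, pad = 10)
  expect_warning(tr0 <- principal_axes_prealign(ell, ell), NA)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 0.5)
  expect_equal(ctmorph:::rotation_matrix(tr0$rotation), diag(3),
               tolerance = 0.05)
  # pure translation by (12, -7, 5): build the moving mask by shifting
  d <- dim(ell)
  moving <- array(FALSE, d)
  src <- ell[1:(d[1] - 12), 8:d[2], 1:(d[3] - 5)]
  moving[13:d[1], 1:(d[2] - 7), 6:d[3]] <- src
  tr <- principal_axes_prealign(ell, moving)
  expect_equal(tr$translation, c(12, -7, 5), tolerance = 0.5)
  # a ball is degenerate: centroid-only path with warning
  expect_warning(trb <- principal_axes_prealign(make_ball(10),
                                                make_ball(10)),
                 "centroid")
  expect_equal(trb$rotation, c(0, 0, 0))
})

test_that("xor_fraction matches a direct voxel count and its properties", {
  set.seed(12)
  a <- array(runif(32^3) < 0.4, c(32, 32, 32))
  b <- array(runif(32^3) < 0.4, c(32, 32, 32))
  c3 <- array(runif(32^3) < 0.4, c(32, 32, 32))
  direct <- 100 * sum(a != b) / length(a)
  expect_equal(xor_fraction(a, b), direct)
  expect_equal(xor_fraction(a, b), xor_fraction(b, a))
  expect_equal(xor_fraction(a, a), 0)
  expect_equal(xor_fraction(a, !a), 100)
  expect_lte(xor_fraction(a, c3),
             xor_fraction(a, b) + xor_fraction(b, c3) + 1e-12)
  expect_error(xor_fraction(a, array(FALSE, c(8, 8, 8))), "differ")
})

test_that("corrected_cell_difference subtracts the non-cell fraction", {
  expect_equal(corrected_cell_difference(7.8, 1.7), 6.1)
  expect_equal(corrected_cell_difference(4.2, 0), 4.2)
  expect_equal(corrected_cell_difference(5, 5), 0)
  expect_error(corrected_cell_difference(3, 4), "within")
})

test_that("self-registration returns the identity", {
  ph <- generate_tissue(phantom_spec(shape = c(64, 64, 64),
                                     random_seed = 19))
  reg <- register_volumes(ph$greyscale, ph$greyscale, capture_range = 8)
  expect_equal(reg$transform$status, "converged")
  expect_gte(reg$metric, 0.999)
  expect_lt(max(abs(reg$transform$translation)), 0.1)
  expect_lt(max(abs(reg$transform$scale - 1)), 0.001)
})

test_that("registration flags disjoint content instead of silently
          passing", {
  a <- array(0, c(48, 48, 48)); a[5:15, 5:15, 5:15] <- 200
  b <- array(0, c(48, 48, 48)); b[35:45, 35:45, 35:45] <- 200
  set.seed(1)
  a <- a + array(runif(48^3, 0, 4), dim(a))
  b <- b + array(runif(48^3, 0, 4), dim(b))
  reg <- register_volumes(ctm_volume(a, 1), ctm_volume(b, 1),
                          capture_range = 4)
  expect_equal(reg$transform$status, "failed")
})

test_that("label resampling stays binary under transforms", {
  lab <- ctm_labels(array(sample(0:3, 20^3, TRUE), c(20, 20, 20)), 1)
  tr <- ctm_transform(translation = c(0.4, -0.3, 0.2),
                      center = c(9.5, 9.5, 9.5))
  out <- apply_transform(lab, tr)
  expect_true(all(out$data %in% 0:3))
  expect_s3_class(out, "ctm_labels")
})
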