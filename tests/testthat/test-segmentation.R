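test_that("two-level Otsu separates a well-separated bimodal volume", {
  set.seed(2)
  vals <- sample(c(10, 200), 40^3, replace = TRUE)
  vol <- ctm_volume(array(vals, c(40, 40, 40)), 2.5, 8L)
  cl <- classify_intensities(vol, 2L)
  expect_gte(cl$thresholds[1], 10)
  expect_lt(cl$thresholds[1], 200)
  expect_true(all((cl$data == 1L) == (vol$data == 200)))
  expect_error(classify_intensities(
    ctm_volume(array(7, c(8, 8, 8)), 1, 8L), 2L), "constant")
})

test_that("Sobel magnitude is zero on constant input and matches direct
          convolution", {
  expect_true(all(sobel_edge_magnitude(array(42, c(5, 5, 5))) == 0))
  set.seed(8)
  patch <- array(runif(7^3, 0, 255), c(7, 7, 7))
  ours <- sobel_edge_magnitude(patch)
  ref <- oracle_sobel(patch)
  inner <- !is.na(ref)
  expect_equal(ours[inner], ref[inner], tolerance = 1e-10)
  # axis-aligned step: maximal response on the step plane
  step <- array(0, c(9, 9, 9))
  step[, , 5:9] <- 100
  mag <- sobel_edge_magnitude(step)
  expect_equal(which(mag[5, 5, ] == max(mag)), c(4, 5))
  # 90-degree axis permutation permutes the magnitudes
  permuted <- aperm(patch, c(2, 3, 1))
  expect_equal(aperm(ours, c(2, 3, 1)), sobel_edge_magnitude(permuted),
               tolerance = 1e-10)
})

test_that("morphological_clean despeckles and opens as specified", {
  a <- array(FALSE, c(9, 9, 9))
  a[5, 5, 5] <- TRUE
  expect_false(any(morphological_clean(a, 2L, 0)))
  # two diagonally touching voxels are 26-adjacent: one component, kept
  b <- array(FALSE, c(9, 9, 9))
  b[4, 4, 4] <- b[5, 5, 5] <- TRUE
  expect_equal(sum(morphological_clean(b, 2L, 0)), 2L)
  # every surviving component has >= min voxels (flood-fill oracle)
  set.seed(17)
  m <- array(runif(24^3) < 0.35, c(24, 24, 24))
  cleaned <- morphological_clean(m, 10L, 0)
  lab <- oracle_components(cleaned)
  if (max(lab) > 0) expect_true(all(tabulate(lab) >= 10))
  # output of opening is a subset of the input
  opened <- morphological_clean(m, 0L, 1)
  expect_true(all(m[opened]))
})

test_that("watershed separates two merged balls along the equidistant
          plane", {
  tb <- make_two_balls(r = 10, sep = 16)
  lab <- watershed_separate(tb$mask, h = 2)
  ids <- sort(unique(as.integer(lab$data[lab$data > 0])))
  expect_length(ids, 2L)
  # every foreground voxel gets exactly one label
  expect_equal(sum(lab$data > 0), sum(tb$mask))
  d <- dim(tb$mask)
  c1 <- c((d[1]) / 2, tb$centers_y[1], (d[3]) / 2)
  c2 <- c((d[1]) / 2, tb$centers_y[2], (d[3]) / 2)
  ref <- oracle_two_seed_split(tb$mask, c1, c2)
  # split surface within one voxel of the equidistant plane: voxels more
  # than 1 voxel away from the plane must agree with the oracle side
  co <- arrayInd(which(tb$mask), d)
  away <- abs(co[, 2] - tb$mid_y) > 1
  ours <- lab$data[tb$mask]
  # align label ids with oracle sides by majority vote
  side1 <- as.integer(names(which.max(table(ours[ref[tb$mask] == 1L]))))
  agree <- (ours == side1) == (ref[tb$mask] == 1L)
  expect_true(all(agree[away]))
})

test_that("watershed handles balls and empty masks", {
  ball <- make_ball(8)
  lab <- watershed_separate(ball, h = 2)
  expect_equal(max(lab$data), 1L)
  empty <- watershed_separate(array(FALSE, c(8, 8, 8)))
  expect_equal(max(empty$data), 0L)
})

test_that("border_kill removes exactly the face-touching labels", {
  a <- array(0L, c(10, 10, 10))
  a[1, 2, 2] <- 1L           # touches z face
  a[5:6, 5:6, 5:6] <- 2L     # interior
  lab <- ctm_labels(a, 2.5)
  out <- border_kill(lab)
  expect_false(any(out$data == 1L))
  expect_identical(which(out$data == 2L), which(a == 2L))
  # random labels: match the face-scan oracle
  set.seed(23)
  m <- array(runif(20^3) < 0.3, c(20, 20, 20))
  wl <- watershed_separate(m, h = 1)
  killed <- border_kill(wl)
  gone <- setdiff(which(tabulate(wl$data) > 0),
                  which(tabulate(killed$data) > 0))
  expect_setequal(gone, oracle_border_labels(wl$data))
})

test_that("apply_filters implements the published cutoffs exactly", {
  cells <- data.frame(
    label_id = 1:3,
    volume_um3 = pi / 6 * c(30, 100, 250)^3,
    equivalent_diameter_um = c(30, 100, 250),
    surface_area_um2 = 1,
    sphericity = 0.9, anisotropy = 0.1,
    centroid_z_um = 0, centroid_y_um = 0, centroid_x_um = 0,
    touches_border = FALSE, structure_class = "cell")
  apple <- preset_filter("apple")
  kept <- apply_filters(cells, apple)
  expect_equal(kept$equivalent_diameter_um, 100)
  # no bounds -> identity; idempotent
  expect_identical(apply_filters(cells, filter_spec()), cells)
  expect_identical(apply_filters(kept, apple), kept)
  # sphericity cut is strict
  cells$sphericity <- 0.75
  expect_equal(nrow(apply_filters(cells, apple)), 0L)
})

test_that("preset filters carry the published values", {
  a <- preset_filter("apple")
  expect_equal(c(a$d_min, a$d_max, a$sphericity_min), c(40, 200, 0.75))
  p <- preset_filter("pear")
  expect_null(p$d_min)
  expect_equal(c(p$d_max, p$sphericity_min), c(200, 0.75))
  expect_equal(preset_filter("tomato")$d_min, 100)
  expect_equal(preset_filter("tomato", tomato_debris = "methods")$d_min, 80)
})

test_that("recover_volume grows monotonically and never merges labels", {
  # two eroded labels separated by a bright wall
  a <- array(0L, c(12, 20, 12))
  a[4:9, 3:8, 4:9] <- 1L
  a[4:9, 13:18, 4:9] <- 2L
  allowed <- array(TRUE, dim(a))
  edge <- array(0, dim(a))
  edge[, 10:11, ] <- 100  # bright wall between them
  lab <- ctm_labels(a, 1)
  expect_identical(recover_volume(lab, allowed, edge, 0L)$data, a)
  grown <- recover_volume(lab, allowed, edge, 100L, ridge_quantile = 0.5)
  expect_true(all(grown$data[a > 0L] == a[a > 0L]))  # monotone
  expect_equal(sort(unique(as.integer(grown$data[grown$data > 0]))),
               c(1L, 2L))
  expect_false(any(grown$data[, 10:11, ] > 0))  # blocked at the wall
})

test_that("recovery on a phantom restores eroded cells close to truth", {
  ph <- enhanced_phantom_96()
  cl <- ctmorph:::classify_enhanced(ph$greyscale)
  clean <- morphological_clean(cl$data == 1L, 27L, 1)
  edges <- sobel_edge_magnitude(ph$greyscale)
  lab <- watershed_separate(clean, edge_map = edges, h = 2,
                            voxel_size = 2.5)
  bright <- cl$data == cl$n_classes - 1L
  grow <- (cl$data == 1L) | bright
  rec <- recover_volume(lab, grow, edges, 4L, ridge_quantile = 1)
  bk <- border_kill(rec)
  tl <- ph$truth_labels$data
  ids <- which(tabulate(bk$data) > 0)
  tv <- tabulate(tl)
  sv <- tabulate(bk$data)
  relerr <- vapply(ids, function(id) {
    tt <- tl[bk$data == id]
    tt <- tt[tt > 0]
    bt <- as.integer(names(which.max(table(tt))))
    abs(sv[id] - tv[bt]) / tv[bt]
  }, numeric(1))
  expect_lt(median(relerr), 0.05)
})

test_that("vasculature and stone-cell clusters are recovered from an
          enhanced phantom", {
  spec <- phantom_spec(shape = c(224, 96, 96), target_porosity = 0.10,
                       contrast_mode = TRUE, random_seed = 9)
  ph <- generate_tissue(spec)
  set.seed(42)
  ph <- add_inclusions(ph, vessel_radius = 25, cluster_diameter = 100,
                       n_clusters = 3)
  res <- run_analysis(run_config(ph$greyscale, mode = "enhanced",
                                 preset = "custom", seed = 9))
  recs <- res$structures$records
  tr_s <- ph$truth_structures$data
  vid <- recs$label[recs$class == "vasculature"]
  expect_length(vid, 1L)
  vmask <- res$structures$labels$data %in% vid
  vt <- tr_s == 1L
  expect_gt(2 * sum(vmask & vt) / (sum(vmask) + sum(vt)), 0.8)
  bid <- recs$label[recs$class == "brachysclereid"]
  expect_length(bid, 3L)
  bmask <- res$structures$labels$data %in% bid
  bt <- tr_s > 1L
  expect_gt(2 * sum(bmask & bt) / (sum(bmask) + sum(bt)), 0.8)
})

test_that("dense structures are absent in control scans, with warning", {
  ph <- generate_tissue(phantom_spec(shape = c(48, 48, 48),
                                     random_seed = 3))
  cl <- classify_intensities(ph$greyscale, 2L)
  expect_warning(out <- extract_dense_structures(cl, voxel_size = 2.5),
                 "control")
  expect_equal(nrow(out$records), 0L)
  expect_equal(max(out$labels$data), 0L)
})
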