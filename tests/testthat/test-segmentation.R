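# Adaptive thresholding, morphological cleanup, watershed, filters.

test_that("a constant image produces an empty mask", {
  img <- flat_image(n = 400)
  mask <- binarize_adaptive(img)
  expect_false(any(mask))
})

test_that("block size must fit inside the image", {
  expect_error(binarize_adaptive(flat_image(n = 128)), "block_size_px")
  expect_error(segmentation_params(block_size_px = 300), "odd")
  expect_error(segmentation_params(n_dilations = -1), "n_dilations")
})

test_that("thresholding covers a rod footprint and little background", {
  sc <- single_rod_scene(length_nm = 300, orientation_deg = 25, n = 1024)
  mask <- binarize_adaptive(sc$image)
  truth <- scene_truth_mask(sc)
  expect_gt(sum(mask & truth) / sum(truth), 0.90)
  expect_lt(sum(mask & !truth) / sum(!truth), 0.01)
})

test_that("binarisation is intensity-affine invariant and polarity-symmetric", {
  sc <- render_scene(scene_params(n_rods = 3, image_size_px = 512),
                     seed = 9)
  mask <- binarize_adaptive(sc$image)
  aff <- micrograph(0.4 * sc$image$pixels + 3, sc$image$pixel_size_nm)
  expect_identical(binarize_adaptive(aff), mask)
  inv <- micrograph(1 - sc$image$pixels, sc$image$pixel_size_nm)
  expect_identical(
    binarize_adaptive(inv, segmentation_params(polarity = "bright_objects")),
    mask)
})

test_that("cleanup removes small objects, keeps large, fills small holes", {
  p <- segmentation_params()
  # 40x40 square: 1600 px, below the 2000 px cutoff after erosion
  expect_false(any(morphological_cleanup(rect_mask(400, 100, 139, 100, 139), p)))
  # 100x100 square survives and ends at least as large as it started
  # (net erosion + 5 dilations)
  big <- morphological_cleanup(rect_mask(400, 100, 199, 100, 199), p)
  expect_gte(sum(big), 100 * 100)
  expect_true(all(big[100:199, 100:199]))
  # 10x10 interior hole (100 px < 500) is filled
  holed <- rect_mask(400, 100, 199, 100, 199)
  holed[140:149, 140:149] <- FALSE
  cleaned <- morphological_cleanup(holed, p)
  expect_true(all(cleaned[140:149, 140:149]))
  # a large hole (40x40 = 1600 px > 500) is preserved
  holed2 <- rect_mask(400, 50, 349, 50, 349)
  holed2[150:250, 150:250] <- FALSE
  cleaned2 <- morphological_cleanup(holed2, p)
  expect_false(any(cleaned2[170:230, 170:230]))
})

test_that("watershed keeps single rods whole and splits touching pairs", {
  # isolated capsule -> one label
  sc <- single_rod_scene(length_nm = 98, orientation_deg = 40, n = 512)
  mask <- morphological_cleanup(binarize_adaptive(sc$image))
  labs <- watershed_split(mask, sc$image$pixel_size_nm)
  expect_equal(labs$n_objects, 1L)

  # two parallel capsules separated by clear background -> two labels
  sc2 <- render_scene(
    scene_params(image_size_px = 512, gaussian_sd = 0,
                 gradient_amplitude = 0),
    seed = 2,
    rods = data.frame(center_row_px = c(180, 330),
                      center_col_px = c(256, 256),
                      orientation_deg = 0, length_nm = 98, width_nm = 18))
  mask2 <- morphological_cleanup(binarize_adaptive(sc2$image))
  labs2 <- watershed_split(mask2, sc2$image$pixel_size_nm)
  expect_equal(labs2$n_objects, 2L)

  # two rods touching tip-to-tip at an angle: the contact is a thin
  # concave neck, which watershed resolves into two objects
  px <- 0.3482
  P <- c(256, 300)                       # contact point (row, col)
  d1 <- c(0, 1)                          # along-axis unit vectors
  d2 <- c(-sin(40 * pi / 180), cos(40 * pi / 180))
  ctr1 <- P - (49 - 2) / px * d1         # 98 nm rods, 2 nm tip overlap
  ctr2 <- P + (49 - 2) / px * d2
  sc3 <- render_scene(
    scene_params(image_size_px = 512, gaussian_sd = 0,
                 gradient_amplitude = 0),
    seed = 5,
    rods = data.frame(center_row_px = c(ctr1[1], ctr2[1]),
                      center_col_px = c(ctr1[2], ctr2[2]),
                      orientation_deg = c(0, 40),
                      length_nm = 98, width_nm = 18))
  mask3 <- morphological_cleanup(binarize_adaptive(sc3$image))
  expect_equal(max(nanorodem:::label_components(mask3)), 1L)  # merged
  labs3 <- watershed_split(mask3, sc3$image$pixel_size_nm)
  expect_equal(labs3$n_objects, 2L)
})

test_that("parallel side-by-side rogue pairs merge and are filtered out", {
  # full-length lateral contact leaves no waist for watershed; the
  # merged object is too wide to be one rod and the minor-axis rule
  # eliminates it
  sc <- render_scene(scene_params(image_size_px = 512, n_rods = 0,
                                  n_pairs_side_by_side = 1,
                                  rod_length_nm = 98, side_pair_gap_nm = 2,
                                  gaussian_sd = 0, gradient_amplitude = 0),
                     seed = 5)
  mask <- morphological_cleanup(binarize_adaptive(sc$image))
  labs <- watershed_split(mask, sc$image$pixel_size_nm)
  expect_equal(labs$n_objects, 1L)
  idx <- which(labs$labels == 1L, arr.ind = TRUE)
  expect_gt(nanorodem:::minor_axis_px(idx) * labs$pixel_size_nm, 40)
  expect_equal(filter_objects(labs)$n_objects, 0L)
})

test_that("filters retain exactly the rod-like object", {
  px <- 0.3482
  n <- 400
  lab <- matrix(0L, n, n)
  # object 1: 1000 px blob -> area 121.2 nm^2 < 500, eliminated
  lab[20:44, 20:59][seq_len(1000)] <- 1L
  # object 2: wide blob, minor axis ~45 nm (129 px square) -> eliminated
  sq <- round(45 / px / 1.1547)  # moment minor axis of a square = 1.1547 s
  lab[200:(200 + sq - 1), 200:(200 + sq - 1)] <- 2L
  # object 3: 49x18 nm capsule -> retained
  sc <- single_rod_scene(length_nm = 49, orientation_deg = 10, n = n)
  caps <- which(scene_truth_mask(sc) & lab == 0L)
  lab[caps] <- 3L
  lm <- label_map(lab, px)
  out <- filter_objects(lm)
  expect_equal(out$n_objects, 1L)
  kept <- which(out$labels == 1L)
  expect_setequal(kept, caps)
})

test_that("every retained object satisfies both filter predicates", {
  sc <- render_scene(scene_params(n_rods = 5, n_debris = 4,
                                  image_size_px = 1024), seed = 13)
  seg <- segment_micrograph(sc$image)
  p <- segmentation_params()
  for (k in seq_len(seg$n_objects)) {
    idx <- which(seg$labels == k, arr.ind = TRUE)
    expect_gte(px_to_nm(nrow(idx), seg$pixel_size_nm, "area"),
               p$min_area_nm2)
    expect_lte(nanorodem:::minor_axis_px(idx) * seg$pixel_size_nm,
               p$max_minor_axis_nm)
  }
})

test_that("well-separated rods are recovered exactly and deterministically", {
  sc <- render_scene(scene_params(n_rods = 10, min_gap_nm = 54),
                     seed = 21)
  seg1 <- segment_micrograph(sc$image)
  expect_equal(seg1$n_objects, 10L)
  seg2 <- segment_micrograph(sc$image)
  expect_identical(seg1$labels, seg2$labels)
})

test_that("8-connected labelling merges diagonal touches", {
  m <- matrix(FALSE, 70, 70)
  m[10:20, 10:20] <- TRUE
  m[21:30, 21:30] <- TRUE   # touches only diagonally at (20,20)-(21,21)
  lab <- nanorodem:::label_components(m)
  expect_equal(max(lab), 1L)
})
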