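# Feret diameter, Pythagorean length, per-object measurement records.

test_that("feret_max handles degenerate and rectangular objects exactly", {
  # one pixel: corner-to-corner of its unit square
  expect_equal(feret_max(cbind(5, 9), 0.3482), sqrt(2) * 0.3482)
  # axis-aligned 141x52 rectangle: diagonal of the corner footprint
  idx <- rect_pixels(1, 141, 1, 52)
  expect_equal(feret_max(idx, 0.3482), sqrt(141^2 + 52^2) * 0.3482,
               tolerance = 1e-12)
  expect_error(feret_max(matrix(numeric(0), ncol = 2), 1), "empty")
})

test_that("feret_max equals the exhaustive pairwise oracle on random blobs", {
  set.seed(71)
  done <- 0
  while (done < 15) {
    idx <- random_blob(max_px = 5000)
    if (is.null(idx)) next
    done <- done + 1
    expect_equal(feret_max(idx, 0.3482), feret_oracle(idx, 0.3482),
                 tolerance = 1e-12)
  }
})

test_that("rod_length applies the Pythagorean width correction", {
  expect_equal(rod_length(52.20), 48.99837, tolerance = 1e-5)
  expect_equal(rod_length(18), 0)
  expect_true(is.na(rod_length(10)))
  expect_error(rod_length(-1), ">= 0")
  # round trip: a rod of length L has Feret sqrt(L^2 + W^2)
  L <- c(0, 5, 49, 98, 147, 257, 300)
  expect_equal(rod_length(sqrt(L^2 + 18^2)), L)
  # monotone in F
  f <- seq(18, 400, by = 7)
  expect_true(all(diff(rod_length(f)) > 0))
})

test_that("measure_rods produces one flagged record per object", {
  empty <- label_map(matrix(0L, 128, 128), 0.3482)
  expect_equal(nrow(measure_rods(empty)), 0L)

  sc <- single_rod_scene(length_nm = 49, orientation_deg = 30, n = 512)
  seg <- segment_micrograph(sc$image)
  m <- measure_rods(seg, source_id = sc$image$source_id)
  expect_equal(nrow(m), 1L)
  expect_false(m$truncated)
  expect_false(m$excluded)
  expect_equal(m$length_nm, 49, tolerance = 0.05)  # +-2 nm discretisation
  expect_gte(m$feret_max_nm, m$minor_axis_nm)
  expect_lte(m$length_nm, m$feret_max_nm)
  expect_equal(m$centroid_row, sc$rods$center_row_px, tolerance = 3)

  # rod half off the frame is flagged truncated
  sct <- single_rod_scene(length_nm = 98, orientation_deg = 0,
                          center = c(256, 2), n = 512)
  segt <- segment_micrograph(sct$image)
  mt <- measure_rods(segt)
  expect_equal(nrow(mt), 1L)
  expect_true(mt$truncated)
})

test_that("measured length is rotation invariant within 3 nm", {
  lens <- vapply(c(0, 30, 45, 90), function(theta) {
    sc <- single_rod_scene(length_nm = 147, orientation_deg = theta,
                           n = 700)
    measure_rods(segment_micrograph(sc$image))$length_nm
  }, numeric(1))
  expect_lt(max(lens) - min(lens), 3)
})

test_that("length recovery across the design sizes is accurate and unbiased", {
  # pooled error over the monomer/dimer/trimer/replicon/virion sizes
  res <- list()
  for (s in 1:2) {
    sc <- render_scene(scene_params(n_rods = 6,
                                    rod_length_nm = c(49, 98, 147),
                                    image_size_px = 1024), seed = 30 + s)
    m <- measure_rods(segment_micrograph(sc$image))
    expect_equal(nrow(m), 6L)
    truth <- sort(sc$rods$true_length_nm)
    res[[s]] <- sort(m$length_nm) - truth
  }
  for (s in 3:4) {
    sc <- render_scene(scene_params(n_rods = 3,
                                    rod_length_nm = c(257, 300),
                                    image_size_px = 1536), seed = 30 + s)
    m <- measure_rods(segment_micrograph(sc$image))
    expect_equal(nrow(m), 3L)
    truth <- sort(sc$rods$true_length_nm)
    res[[s]] <- sort(m$length_nm) - truth
  }
  err <- unlist(res)
  expect_lt(mean(abs(err)), 4)    # mean absolute error
  expect_lt(abs(mean(err)), 2)    # bias
})

test_that("measurement CSV round-trips through write/read", {
  sc <- render_scene(scene_params(n_rods = 4), seed = 17)
  m <- measure_rods(segment_micrograph(sc$image),
                    source_id = sc$image$source_id)
  f <- tempfile(fileext = ".csv")
  write_measurements(m, f)
  back <- read_measurements(f)
  expect_equal(back$length_nm, m$length_nm, tolerance = 1e-6)
  expect_identical(back$truncated, m$truncated)
  expect_identical(names(back), names(m))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_measurements(bad), "missing column")
})
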