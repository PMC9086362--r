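# Micrograph containers, unit conversion, MRC2014 and TIFF round trips.

test_that("micrograph constructor enforces its invariants", {
  expect_s3_class(flat_image(), "micrograph")
  expect_error(micrograph(matrix(0.5, 32, 32), 0.3482), "64x64")
  expect_error(micrograph(matrix(c(NA, runif(64 * 64 - 1)), 64), 0.3482),
               "finite")
  expect_error(micrograph(matrix(0.5, 64, 64), -1), "positive")
  expect_error(micrograph(matrix(0.5, 64, 64), Inf), "positive")
})

test_that("px_to_nm converts lengths and areas and is linear", {
  expect_equal(px_to_nm(100, 0.3482, "length"), 34.82)
  expect_equal(px_to_nm(4122, 0.3482, "area"), 499.7646, tolerance = 1e-6)
  expect_equal(px_to_nm(0, 0.3482, "area"), 0)
  expect_error(px_to_nm(-1, 0.3482), "non-negative")
  a <- runif(20, 0, 500); b <- runif(20, 0, 500)
  expect_equal(px_to_nm(a + b, 0.3482, "length"),
               px_to_nm(a, 0.3482, "length") +
                 px_to_nm(b, 0.3482, "length"))
})

test_that("a hand-constructed MRC2014 file reads back correctly", {
  # Fixture built byte-by-byte from the MRC2014 header layout,
  # independent of the package's writer: 4x3 float32 image, pixel size
  # 3.482 Angstrom (cella_x = nx * 3.482).
  nx <- 4L; ny <- 3L
  vals <- as.numeric(1:12) / 7
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  writeBin(c(nx, ny, 1L, 2L), con, size = 4, endian = "little")
  writeBin(integer(3), con, size = 4, endian = "little")        # nstart
  writeBin(c(nx, ny, 1L), con, size = 4, endian = "little")     # mx my mz
  writeBin(c(nx * 3.482, ny * 3.482, 3.482, 90, 90, 90), con,
           size = 4, endian = "little")                          # cella/b
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")     # map order
  writeBin(c(min(vals), max(vals), mean(vals)), con, size = 4,
           endian = "little")
  writeBin(c(0L, 0L), con, size = 4, endian = "little")         # ispg nsymbt
  writeBin(raw(1024 - 96), con)                                 # rest of hdr
  writeBin(vals, con, size = 4, endian = "little")              # x fastest
  close(con)

  # pixel size comes from the header; too small for the micrograph
  # class, so read the raw structure
  raw_img <- nanorodem:::read_mrc(f)
  expect_equal(raw_img$pixel_size_nm, 0.3482, tolerance = 1e-6)
  expect_equal(dim(raw_img$pixels), c(ny, nx))
  # x is the fastest axis: first stored value is row 1, col 1; the
  # second is row 1, col 2
  f32 <- function(x) readBin(writeBin(x, raw(), size = 4), "double",
                             size = 4, n = length(x))
  expect_equal(raw_img$pixels[1, 2], f32(vals[2]))
  expect_equal(as.vector(t(raw_img$pixels)), f32(vals))
})

test_that("MRC round trip preserves intensities and calibration", {
  set.seed(3)
  sc <- list(image = micrograph(
    nanorodem:::snap_float32(matrix(runif(128 * 128), 128)), 0.3482))
  f <- tempfile(fileext = ".mrc")
  write_micrograph(sc$image, f)
  back <- load_micrograph(f)
  expect_identical(back$pixels, sc$image$pixels)
  expect_equal(back$pixel_size_nm, sc$image$pixel_size_nm,
               tolerance = 1e-6)
})

test_that("TIFF round trip preserves intensities; override sets calibration", {
  sc <- render_scene(scene_params(n_rods = 2, image_size_px = 512),
                     seed = 4)
  f <- tempfile(fileext = ".tif")
  write_micrograph(sc$image, f)
  back <- load_micrograph(f, pixel_size_override = 0.5)
  # 32-bit samples: quantisation at 1/(2^32 - 1)
  expect_equal(back$pixels, sc$image$pixels, tolerance = 1e-9)
  expect_lt(max(abs(back$pixels - sc$image$pixels)), 2^-31)
  expect_equal(back$pixel_size_nm, 0.5)
  expect_error(
    write_micrograph(micrograph(matrix(2, 64, 64), 1), f), "\\[0, 1\\]")
})

test_that("missing calibration falls back to the default with a warning", {
  m <- matrix(runif(64 * 64), 64)
  m <- nanorodem:::snap_float32(m)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, f, bits.per.sample = 32L, compression = "none")
  expect_warning(mg <- load_micrograph(f), "0.3482")
  expect_equal(mg$pixel_size_nm, 0.3482)
})

test_that("RGB images and unknown formats are rejected", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(64 * 64 * 3), c(64, 64, 3)), f)
  expect_error(load_micrograph(f, pixel_size_override = 1),
               "multi-channel")
  expect_error(load_micrograph(tempfile(fileext = ".png")), "not found")
  f2 <- tempfile(fileext = ".xyz"); file.create(f2)
  expect_error(load_micrograph(f2), "format")
})
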