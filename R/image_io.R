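# Calibrated micrograph I/O: MRC2014 and single-page grayscale TIFF.

#' Default pixel calibration (nm per pixel)
#'
#' Edge length of one detector pixel for the acquisition setup this
#' pipeline was developed on (3.482 Angstrom). Used as a last-resort
#' fallback by [load_micrograph()], with a warning.
#' @export
DEFAULT_PIXEL_SIZE_NM <- 0.3482

#' Construct a calibrated micrograph
#'
#' A `micrograph` is a 2D grayscale intensity field together with its
#' physical pixel size. Intensities are kept in whatever units the
#' detector (or generator) produced; segmentation is intensity-scale
#' invariant so no normalisation is applied here.
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param pixel_size_nm physical edge length of one pixel, in nm (> 0).
#' @param source_id free-text provenance (file path or synthetic scene id).
#' @return An object of class `micrograph`: a list with elements
#'   `pixels`, `pixel_size_nm`, `source_id`.
#' @examples
#' m <- micrograph(matrix(runif(128 * 128), 128), pixel_size_nm = 0.3482)
#' @export
micrograph <- function(pixels, pixel_size_nm, source_id = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(dim(pixels) < 64L))
    stop("micrograph must be at least 64x64 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive finite number",
         call. = FALSE)
  structure(list(pixels = pixels,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 source_id = as.character(source_id)[1L]),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px, %.4f nm/px (%.0f x %.0f nm), source: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              nrow(x$pixels) * x$pixel_size_nm,
              ncol(x$pixels) * x$pixel_size_nm, x$source_id))
  invisible(x)
}

#' Load a micrograph from an MRC or TIFF file
#'
#' Reads a single-frame grayscale image and its pixel calibration. For
#' MRC2014 files the pixel size comes from the cell-dimension header; for
#' TIFF it comes from the resolution tags when present. When the file
#' carries no calibration, `pixel_size_override` is used; if that is also
#' missing, the default acquisition calibration
#' [DEFAULT_PIXEL_SIZE_NM] (0.3482 nm) is assumed with a warning.
#'
#' Multi-page TIFFs are read as page 1 with a warning; RGB or
#' higher-dimensional images are rejected.
#'
#' @param path path to an `.mrc`/`.map` or `.tif`/`.tiff` file.
#' @param pixel_size_override optional pixel size in nm, used when the
#'   file has no usable calibration.
#' @return A [micrograph].
#' @seealso [write_micrograph()]
#' @export
load_micrograph <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "map", "mrcs")) {
    dat <- read_mrc(path)
    px <- dat$pixel_size_nm
    pixels <- dat$pixels
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(pages) > 1L)
      warning("multi-page TIFF: using page 1 of ", length(pages))
    img <- pages[[1L]]
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] == 1L) img <- img[, , 1L]
      else stop("multi-channel (RGB) TIFF not supported: ", path,
                call. = FALSE)
    }
    px <- tiff_pixel_size_nm(img)
    pixels <- unclass(as.matrix(img))
    attributes(pixels) <- list(dim = dim(pixels))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (is.null(px) || !is.finite(px) || px <= 0) {
    if (!is.null(pixel_size_override)) {
      px <- pixel_size_override
    } else {
      warning("no pixel size in file metadata and no override given; ",
              "assuming ", DEFAULT_PIXEL_SIZE_NM, " nm/px")
      px <- DEFAULT_PIXEL_SIZE_NM
    }
  }
  micrograph(pixels, pixel_size_nm = px, source_id = path)
}

# Pixel size from TIFF resolution tags (pixels per unit -> nm), if any.
tiff_pixel_size_nm <- function(img) {
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit_nm <- switch(as.character(unit %||% "inch"),
                    inch = 2.54e7, cm = 1e7, NULL)
  if (is.null(unit_nm)) return(NULL)
  unit_nm / xres
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a micrograph to disk
#'
#' MRC output (mode 2, 32-bit float) stores the pixel calibration in the
#' header, so an MRC round trip preserves both intensities and pixel
#' size bit-exactly (for float32-representable intensities). TIFF output
#' uses 32-bit integer samples over \[0, 1\] (quantisation step
#' ~2.3e-10) and carries no calibration: supply `pixel_size_override`
#' when reloading, and use MRC when exact values matter. Intensities
#' outside \[0, 1\] raise an error for TIFF.
#'
#' @param img a [micrograph].
#' @param path destination ending in `.mrc`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "map")) {
    write_mrc(img$pixels, path, pixel_size_nm = img$pixel_size_nm)
  } else if (ext %in% c("tif", "tiff")) {
    if (min(img$pixels) < 0 || max(img$pixels) > 1)
      stop("TIFF output requires intensities in [0, 1]; use MRC instead",
           call. = FALSE)
    tiff::writeTIFF(img$pixels, path, bits.per.sample = 32L,
                    compression = "none")
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Convert pixel measures to physical units
#'
#' @param value pixel count (length) or pixel area; non-negative.
#' @param pixel_size_nm pixel edge length in nm.
#' @param kind `"length"` (nm = px * nm/px) or `"area"`
#'   (nm^2 = px * (nm/px)^2).
#' @return value in nm or nm^2.
#' @examples
#' px_to_nm(100, 0.3482, "length")  # 34.82
#' px_to_nm(4122, 0.3482, "area")   # ~499.8, the 500 nm^2 area filter
#' @export
px_to_nm <- function(value, pixel_size_nm, kind = c("length", "area")) {
  kind <- match.arg(kind)
  if (any(value < 0)) stop("`value` must be non-negative", call. = FALSE)
  if (pixel_size_nm <= 0) stop("`pixel_size_nm` must be positive",
                               call. = FALSE)
  if (kind == "length") value * pixel_size_nm else value * pixel_size_nm^2
}

# ---------------------------------------------------------------------------
# Minimal MRC2014 reader/writer (little-endian). Header words used:
#   1-3  nx, ny, nz        4  mode (0 int8, 1 int16, 2 float32, 6 uint16)
#   11-13 cella (cell dimensions, Angstrom)   24 nsymbt (extended header bytes)
# Pixel size = cella_x / nx Angstrom. Data follow the 1024-byte header plus
# the extended header, in column-fastest (x fastest) order.
# ---------------------------------------------------------------------------

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L)
    stop("truncated MRC header: ", path, call. = FALSE)
  int_at <- function(i, signed = TRUE)
    readBin(hdr_raw[(4L * (i - 1L) + 1L):(4L * i)], "integer", size = 4L,
            endian = "little")
  flt_at <- function(i)
    readBin(hdr_raw[(4L * (i - 1L) + 1L):(4L * i)], "double", size = 4L,
            endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3); mode <- int_at(4)
  if (nx <= 0 || ny <= 0 || nx > 65536 || ny > 65536)
    stop("unreadable MRC header (bad dimensions): ", path, call. = FALSE)
  if (nz > 1L)
    warning("MRC stack with ", nz, " sections: using section 1")
  if (nz < 1L) stop("empty MRC file: ", path, call. = FALSE)
  cella_x <- flt_at(11)
  nsymbt <- int_at(24)
  n <- as.numeric(nx) * ny
  seek(con, where = 1024L + nsymbt, origin = "start")
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode ", mode, call. = FALSE))
  if (length(vals) < n) stop("truncated MRC data: ", path, call. = FALSE)
  # MRC stores x fastest; map x -> image column, y -> image row.
  pixels <- t(matrix(as.numeric(vals), nrow = nx, ncol = ny))
  pixel_size_nm <- if (is.finite(cella_x) && cella_x > 0)
    (cella_x / nx) / 10 else NULL
  list(pixels = pixels, pixel_size_nm = pixel_size_nm)
}

write_mrc <- function(pixels, path, pixel_size_nm) {
  nx <- ncol(pixels); ny <- nrow(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, 1L))                      # nx ny nz
  wi(2L)                                 # mode 2: float32
  wi(c(0L, 0L, 0L))                      # nxstart nystart nzstart
  wi(c(nx, ny, 1L))                      # mx my mz
  wf(c(nx * pixel_size_nm * 10, ny * pixel_size_nm * 10, pixel_size_nm * 10))
  wf(c(90, 90, 90))                      # cell angles
  wi(c(1L, 2L, 3L))                      # mapc mapr maps
  wf(c(min(pixels), max(pixels), mean(pixels)))  # dmin dmax dmean
  wi(c(0L, 0L))                          # ispg nsymbt
  writeBin(raw(100L), con)               # extra (words 26-50)
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(0)                                  # rms (not computed)
  wi(0L)                                 # nlabl
  writeBin(raw(800L), con)               # labels
  wf(as.double(t(pixels)))               # x fastest
  invisible(path)
}
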