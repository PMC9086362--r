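# Per-object geometry: maximum Feret diameter and Pythagorean rod length.

#' Measurement parameters
#'
#' @param rod_width_nm known nanorod width in nm. TMV-like rods are
#'   18 nm in external diameter; the Feret-to-length correction removes
#'   the corner-to-corner inflation due to this width.
#' @return A list of class `measurement_params`.
#' @export
measurement_params <- function(rod_width_nm = 18) {
  if (rod_width_nm <= 0) stop("`rod_width_nm` must be > 0", call. = FALSE)
  structure(list(rod_width_nm = rod_width_nm),
            class = "measurement_params")
}

#' Maximum Feret diameter of one object
#'
#' The largest caliper distance across the object: the maximum Euclidean
#' distance between any two points of its pixel footprint, with each
#' pixel treated as a unit square (so the measure runs corner to corner,
#' matching the rod's "two most distant corners" and avoiding a
#' systematic one-pixel underestimate). Computed exactly via the convex
#' hull of the boundary-pixel corners.
#'
#' @param object_pixels two-column matrix of (row, col) pixel
#'   coordinates, 1-based.
#' @param pixel_size_nm pixel calibration in nm.
#' @return Feret maximum diameter in nm.
#' @examples
#' feret_max(cbind(1, 1), 0.3482)  # single pixel: sqrt(2) * 0.3482
#' @export
feret_max <- function(object_pixels, pixel_size_nm) {
  if (is.null(dim(object_pixels)))
    object_pixels <- matrix(object_pixels, ncol = 2L)
  if (nrow(object_pixels) == 0L)
    stop("empty object", call. = FALSE)
  corners <- pixel_corners(boundary_pixels(object_pixels))
  h <- chull(corners)
  hp <- corners[h, , drop = FALSE]
  max_pairwise_dist(hp) * pixel_size_nm
}

# Pixels with fewer than four 4-neighbours inside the object (plus
# singletons); sufficient support for the convex hull.
boundary_pixels <- function(idx) {
  if (nrow(idx) <= 8L) return(idx)
  key <- function(r, c) r + c * (max(idx[, 1L]) + 2L)
  tab <- key(idx[, 1L], idx[, 2L])
  n4 <- match(key(idx[, 1L] - 1L, idx[, 2L]), tab, 0L) > 0L
  n4 <- n4 + (match(key(idx[, 1L] + 1L, idx[, 2L]), tab, 0L) > 0L)
  n4 <- n4 + (match(key(idx[, 1L], idx[, 2L] - 1L), tab, 0L) > 0L)
  n4 <- n4 + (match(key(idx[, 1L], idx[, 2L] + 1L), tab, 0L) > 0L)
  idx[n4 < 4L, , drop = FALSE]
}

# The four corners of each pixel's unit-square footprint, in px units
# (pixel (r, c) occupies [r-1, r] x [c-1, c]).
pixel_corners <- function(idx) {
  r <- idx[, 1L]; c <- idx[, 2L]
  cbind(c(r - 1L, r - 1L, r, r), c(c - 1L, c, c - 1L, c))
}

max_pairwise_dist <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(0)
  sqrt(max(stats::dist(pts)^2))
}

#' Rod length from the Feret diameter
#'
#' For a rigid rod of width W lying at any angle, the maximum Feret
#' diameter F is the diagonal of its L x W footprint, so the length is
#' recovered as L = sqrt(F^2 - W^2). Objects with F < W cannot be rods
#' of that width and get `NA`.
#'
#' @param feret_max_nm Feret maximum diameter(s) in nm, >= 0.
#' @param params a [measurement_params].
#' @return Length(s) in nm; `NA` where `feret_max_nm < rod_width_nm`.
#' @examples
#' rod_length(52.20)  # ~49.0
#' rod_length(18)     # 0 at the boundary
#' @export
rod_length <- function(feret_max_nm, params = measurement_params()) {
  if (any(feret_max_nm < 0, na.rm = TRUE))
    stop("`feret_max_nm` must be >= 0", call. = FALSE)
  w <- params$rod_width_nm
  out <- rep(NA_real_, length(feret_max_nm))
  ok <- !is.na(feret_max_nm) & feret_max_nm >= w
  out[ok] <- sqrt(feret_max_nm[ok]^2 - w^2)
  out
}

#' Measure every object in a label map
#'
#' Produces one record per labelled object: area, moment-based minor
#' axis, maximum Feret diameter, derived rod length, centroid, and QC
#' flags. `truncated` is `TRUE` when any object pixel lies on the image
#' border (its length is then only a lower bound); `excluded` starts
#' `FALSE` and is toggled by [exclude_rogue()].
#'
#' @param labels a [label_map].
#' @param params a [measurement_params].
#' @param source_id provenance string recorded in every row.
#' @return A data.frame with columns `source_id`, `object_id`,
#'   `area_nm2`, `minor_axis_nm`, `feret_max_nm`, `length_nm`,
#'   `centroid_row`, `centroid_col`, `truncated`, `excluded`.
#' @export
measure_rods <- function(labels, params = measurement_params(),
                         source_id = "unknown") {
  stopifnot(inherits(labels, "label_map"))
  n <- labels$n_objects
  px <- labels$pixel_size_nm
  nr <- nrow(labels$labels); nc <- ncol(labels$labels)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(labels$labels == k, arr.ind = TRUE)
    f <- feret_max(idx, px)
    rows[[k]] <- data.frame(
      source_id = source_id,
      object_id = k,
      area_nm2 = px_to_nm(nrow(idx), px, "area"),
      minor_axis_nm = minor_axis_px(idx) * px,
      feret_max_nm = f,
      length_nm = rod_length(f, params),
      centroid_row = mean(idx[, 1L]) - 0.5,   # 0-based pixel centres
      centroid_col = mean(idx[, 2L]) - 0.5,
      truncated = any(idx[, 1L] == 1L | idx[, 1L] == nr |
                      idx[, 2L] == 1L | idx[, 2L] == nc),
      excluded = FALSE,
      stringsAsFactors = FALSE)
  }
  if (n == 0L) return(empty_measurements())
  do.call(rbind, rows)
}

empty_measurements <- function() {
  data.frame(source_id = character(), object_id = integer(),
             area_nm2 = numeric(), minor_axis_nm = numeric(),
             feret_max_nm = numeric(), length_nm = numeric(),
             centroid_row = numeric(), centroid_col = numeric(),
             truncated = logical(), excluded = logical(),
             stringsAsFactors = FALSE)
}

measurement_columns <- c("source_id", "object_id", "area_nm2",
                         "minor_axis_nm", "feret_max_nm", "length_nm",
                         "centroid_row", "centroid_col", "truncated",
                         "excluded")

#' Write / read a measurement table
#'
#' Plain CSV with the fixed column set produced by [measure_rods()].
#' Numeric values are written with full precision so identical runs give
#' byte-identical files.
#'
#' @param measurements measurement data.frame.
#' @param path CSV path.
#' @return `path` (write) or the measurement data.frame (read).
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(all(measurement_columns %in% names(measurements)))
  out <- measurements[, measurement_columns]
  for (cn in c("area_nm2", "minor_axis_nm", "feret_max_nm", "length_nm",
               "centroid_row", "centroid_col"))
    out[[cn]] <- sprintf("%.6f", out[[cn]])
  out$length_nm[is.na(measurements$length_nm)] <- "NA"
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(measurement_columns, names(m))
  if (length(missing))
    stop("not a measurement CSV; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m$truncated <- as.logical(m$truncated)
  m$excluded <- as.logical(m$excluded)
  m
}
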