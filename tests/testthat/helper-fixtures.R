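# Shared fixtures, built in code at test time.

# Constant-background micrograph with optional painted regions.
flat_image <- function(n = 128, level = 0.7, pixel_size_nm = 0.3482) {
  micrograph(matrix(level, n, n), pixel_size_nm, source_id = "flat")
}

# Binary mask with a filled axis-aligned rectangle.
rect_mask <- function(n, r0, r1, c0, c1) {
  m <- matrix(FALSE, n, n)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# Pixel index matrix of a filled rectangle (for feret/minor-axis input).
rect_pixels <- function(r0, r1, c0, c1)
  as.matrix(expand.grid(r0:r1, c0:c1))

# Exhaustive O(n^2) Feret oracle: max pairwise distance over the unit
# square corners of the object's outline pixels. The maximum caliper
# distance is always attained on the outline, which is derived here by
# mask erosion -- a route independent of the package's convex-hull
# implementation.
feret_oracle <- function(idx, pixel_size_nm) {
  pad <- 2L
  off_r <- min(idx[, 1]) - pad; off_c <- min(idx[, 2]) - pad
  m <- matrix(0, max(idx[, 1]) - off_r + pad + 1L,
              max(idx[, 2]) - off_c + pad + 1L)
  m[cbind(idx[, 1] - off_r + 1L, idx[, 2] - off_c + 1L)] <- 1
  inner <- EBImage::erode(m, EBImage::makeBrush(3, "box"))
  b <- which(m > 0 & inner == 0, arr.ind = TRUE)
  r <- b[, 1] + off_r - 1L; c <- b[, 2] + off_c - 1L
  pts <- unique(cbind(c(r - 1, r - 1, r, r), c(c - 1, c, c - 1, c)))
  sqrt(max(dist(pts)^2)) * pixel_size_nm
}

# Pooled pipeline measurements over as many synthetic scenes as needed
# to reach `total_rods` rods of the given true length(s).
sim_batch <- function(total_rods, length_nm, image_size_px = 1024,
                      per_scene = 12, base_seed = 1000, ...) {
  out <- list()
  got <- 0; s <- 0
  while (got < total_rods) {
    s <- s + 1
    sc <- tryCatch(
      render_scene(scene_params(n_rods = per_scene,
                                rod_length_nm = length_nm,
                                image_size_px = image_size_px, ...),
                   seed = base_seed + s),
      error = function(e) NULL)   # crowded placement: skip this seed
    if (is.null(sc)) next
    m <- measure_rods(segment_micrograph(sc$image),
                      source_id = sc$image$source_id)
    out[[length(out) + 1L]] <- m
    got <- got + nrow(m)
  }
  do.call(rbind, out)
}

# Random connected blob of at most max_px pixels: dilated random walk.
random_blob <- function(max_px = 5000, n = 200) {
  pos <- matrix(c(n %/% 2, n %/% 2), ncol = 2)
  steps <- sample(1:4, size = max(10, max_px %/% 12), replace = TRUE)
  moves <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[steps, , drop = FALSE]
  path <- apply(moves, 2, cumsum)
  path <- sweep(path, 2, c(n %/% 2, n %/% 2), "+")
  path <- path[path[, 1] > 3 & path[, 1] < n - 3 &
               path[, 2] > 3 & path[, 2] < n - 3, , drop = FALSE]
  m <- matrix(0, n, n)
  m[rbind(matrix(c(n %/% 2, n %/% 2), ncol = 2), path)] <- 1
  m <- EBImage::dilate(m, EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(m)
  idx <- which(lab == lab[n %/% 2, n %/% 2], arr.ind = TRUE)
  if (nrow(idx) > max_px) idx <- NULL  # caller retries
  idx
}

# A noiseless scene of a single explicit rod.
single_rod_scene <- function(length_nm = 49, orientation_deg = 0,
                             center = NULL, n = 512, width_nm = 18,
                             gaussian_sd = 0, seed = 1) {
  if (is.null(center)) center <- c(n / 2, n / 2)
  render_scene(
    scene_params(image_size_px = n, gaussian_sd = gaussian_sd,
                 gradient_amplitude = 0),
    seed = seed,
    rods = data.frame(center_row_px = center[1], center_col_px = center[2],
                      orientation_deg = orientation_deg,
                      length_nm = length_nm, width_nm = width_nm))
}

# Minimal measurement frame for report-level tests.
meas_frame <- function(lengths, source_id = "s", truncated = FALSE,
                       excluded = FALSE) {
  if (length(lengths) == 0L) return(nanorodem:::empty_measurements())
  data.frame(source_id = source_id,
             object_id = seq_along(lengths),
             area_nm2 = 800, minor_axis_nm = 20,
             feret_max_nm = sqrt(lengths^2 + 18^2),
             length_nm = lengths,
             centroid_row = 0, centroid_col = 0,
             truncated = truncated, excluded = excluded,
             stringsAsFactors = FALSE)
}
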