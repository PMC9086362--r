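# Segmentation of candidate nanorods: adaptive threshold -> erosion ->
# small-object removal -> dilation -> hole filling -> watershed -> filters.

#' Segmentation parameters
#'
#' Defaults reproduce the published pipeline: adaptive threshold with a
#' 301-pixel block, one erosion, removal of objects under 2000 px,
#' five dilations, filling of holes under 500 px, watershed, then
#' elimination of objects with area under 500 nm^2 or minor axis over
#' 40 nm. The pixel-unit thresholds (block size, 2000 px, 500 px) assume
#' the native 0.3482 nm/px calibration; rescale them for differently
#' binned data.
#'
#' @param block_size_px odd block size (px) of the local-mean adaptive
#'   threshold window.
#' @param threshold_offset subtracted from the local mean before
#'   comparison; 0 marks every pixel darker than its neighbourhood.
#' @param min_object_px connected components smaller than this (px) are
#'   removed after the erosion step.
#' @param n_dilations number of 3x3-cross dilations after small-object
#'   removal.
#' @param max_hole_px enclosed background holes smaller than this (px)
#'   are filled.
#' @param min_area_nm2 objects with area below this (nm^2) are
#'   eliminated.
#' @param max_minor_axis_nm objects with moment-based minor axis above
#'   this (nm) are eliminated.
#' @param polarity `"dark_objects"` for negative stain (rods darker than
#'   background) or `"bright_objects"` for inverted contrast.
#' @param watershed_min_sep_nm minimum separation between watershed
#'   seed maxima of the distance transform; defaults to one rod width so
#'   a single rod is never split along its length.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(block_size_px = 301L,
                                threshold_offset = 0,
                                min_object_px = 2000L,
                                n_dilations = 5L,
                                max_hole_px = 500L,
                                min_area_nm2 = 500,
                                max_minor_axis_nm = 40,
                                polarity = c("dark_objects",
                                             "bright_objects"),
                                watershed_min_sep_nm = 18) {
  polarity <- match.arg(polarity)
  block_size_px <- as.integer(block_size_px)
  if (block_size_px < 3L || block_size_px %% 2L == 0L)
    stop("`block_size_px` must be odd and >= 3", call. = FALSE)
  if (min_object_px < 0 || max_hole_px < 0 || min_area_nm2 < 0 ||
      max_minor_axis_nm < 0 || watershed_min_sep_nm < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  if (n_dilations < 0) stop("`n_dilations` must be >= 0", call. = FALSE)
  structure(list(block_size_px = block_size_px,
                 threshold_offset = threshold_offset,
                 min_object_px = as.integer(min_object_px),
                 n_dilations = as.integer(n_dilations),
                 max_hole_px = as.integer(max_hole_px),
                 min_area_nm2 = min_area_nm2,
                 max_minor_axis_nm = max_minor_axis_nm,
                 polarity = polarity,
                 watershed_min_sep_nm = watershed_min_sep_nm),
            class = "segmentation_params")
}

#' Construct a label map
#'
#' @param labels integer matrix; 0 = background, k >= 1 = object k.
#'   Labels must be consecutive 1..n.
#' @param pixel_size_nm pixel calibration in nm.
#' @return A list of class `label_map` with `labels`, `pixel_size_nm`,
#'   `n_objects`.
#' @export
label_map <- function(labels, pixel_size_nm) {
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(n)))
    stop("labels must be consecutive 1..n_objects", call. = FALSE)
  structure(list(labels = labels, pixel_size_nm = pixel_size_nm,
                 n_objects = n),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d object(s), %.4f nm/px\n",
              nrow(x$labels), ncol(x$labels), x$n_objects,
              x$pixel_size_nm))
  invisible(x)
}

#' Adaptive-threshold binarisation
#'
#' Marks pixels whose intensity falls below (dark polarity) or above
#' (bright polarity) a Gaussian-weighted local mean computed over a
#' `block_size_px` neighbourhood. Because the comparison is local and
#' strict, a constant image yields an empty mask and the result is
#' invariant under affine intensity rescaling `a * img + b`, a > 0.
#'
#' @param img a [micrograph].
#' @param params a [segmentation_params].
#' @return Logical matrix, `TRUE` on candidate-object pixels.
#' @export
binarize_adaptive <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "micrograph"))
  if (params$block_size_px >= min(dim(img$pixels)))
    stop("`block_size_px` must be smaller than both image dimensions",
         call. = FALSE)
  local_mean <- local_gaussian_mean(img$pixels, params$block_size_px)
  scale <- max(img$pixels) - min(img$pixels)
  s <- if (scale > 0) scale else 1
  # tiny slack absorbs FFT round-off so exact ties never count as dark
  off <- params$threshold_offset * s + 1e-9 * s
  if (params$polarity == "dark_objects")
    unclass(img$pixels < local_mean - off)
  else
    unclass(img$pixels > local_mean + off)
}

# Gaussian-weighted local mean over a block_size window, as normalized
# convolution (zero padding divided by the local kernel mass), so the
# mean is unbiased at the image borders. The denominator depends only on
# the image size and block size and is cached across calls.
.mass_cache <- new.env(parent = emptyenv())
local_gaussian_mean <- function(x, block_size_px) {
  sigma <- (block_size_px - 1) / 6   # ~3-sigma support = block size
  brush <- EBImage::makeBrush(block_size_px, shape = "Gaussian",
                              sigma = sigma)
  num <- EBImage::filter2(x, brush, boundary = 0)
  key <- paste(nrow(x), ncol(x), block_size_px, sep = "x")
  den <- .mass_cache[[key]]
  if (is.null(den)) {
    den <- EBImage::filter2(matrix(1, nrow(x), ncol(x)), brush,
                            boundary = 0)
    .mass_cache[[key]] <- den
  }
  num / den
}

#' Morphological cleanup of a binary mask
#'
#' Applies, in order: one erosion (3x3 cross), removal of connected
#' components below `min_object_px`, `n_dilations` dilations (3x3
#' cross), and filling of enclosed holes below `max_hole_px`. The
#' erosion-then-size-filter pass deletes the speckle that adaptive
#' thresholding produces on noisy background; the dilations restore the
#' surviving rods (slightly inflated; see the measurement docs).
#'
#' @param mask logical matrix from [binarize_adaptive()].
#' @param params a [segmentation_params].
#' @return Cleaned logical matrix.
#' @export
morphological_cleanup <- function(mask, params = segmentation_params()) {
  stopifnot(is.matrix(mask))
  mask <- mask * 1
  brush <- EBImage::makeBrush(3L, shape = "diamond")
  mask <- EBImage::erode(mask, brush)
  mask <- remove_small_objects(mask > 0, params$min_object_px)
  mask <- mask * 1
  for (i in seq_len(params$n_dilations))
    mask <- EBImage::dilate(mask, brush)
  fill_small_holes(mask > 0, params$max_hole_px)
}

# Drop 8-connected foreground components with fewer than min_px pixels.
remove_small_objects <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  keep <- tabulate(lab[lab > 0L]) >= min_px
  matrix(lab > 0L & keep[pmax(lab, 1L)], nrow(mask))
}

# Fill 4-connected background holes (not touching the border) smaller
# than max_px.
fill_small_holes <- function(mask, max_px) {
  bg <- EBImage::bwlabel(1 - mask)        # bwlabel is 4-connected
  border_labs <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L],
                          bg[, ncol(bg)]))
  border_labs <- border_labs[border_labs > 0L]
  if (max(bg) == 0L) return(mask)
  sizes <- tabulate(bg[bg > 0L])
  fill <- sizes < max_px
  if (length(border_labs)) fill[border_labs] <- FALSE
  matrix(mask | (bg > 0L & fill[pmax(bg, 1L)]), nrow(mask))
}

# 8-connected labelling: 4-connected pass, then merge labels that touch
# diagonally. Labels are consecutive 1..n.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(unclass(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]    # down-right diagonal
  a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]    # up-right diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(n)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- pairs[k, 1L]; while (parent[ra] != ra) ra <- parent[ra]
      rb <- pairs[k, 2L]; while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]; i
  }, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  unclass(out)
}

#' Watershed splitting of touching objects
#'
#' Separates close-lying rods that merged into one component. Seeds are
#' regional maxima of the (lightly smoothed) Euclidean distance
#' transform, with a minimum peak separation of one rod width
#' (`watershed_min_sep_nm`); foreground pixels are then assigned to
#' seeds by watershed flooding of the negated distance transform. A
#' single rod carries one ridge plateau and yields exactly one label;
#' two rods joined side-by-side with a concave waist carry two ridges
#' and are split at the waist. Each connected component is processed in
#' its own bounding box, so cost scales with foreground area.
#'
#' @param mask cleaned logical matrix ([morphological_cleanup()]).
#' @param pixel_size_nm pixel calibration in nm.
#' @param params a [segmentation_params].
#' @return A [label_map].
#' @export
watershed_split <- function(mask, pixel_size_nm,
                            params = segmentation_params()) {
  stopifnot(is.matrix(mask))
  comp <- label_components(mask)
  n_comp <- max(comp)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (n_comp == 0L)
    return(label_map(out, pixel_size_nm))
  sep_px <- max(3L, as.integer(round(params$watershed_min_sep_nm /
                                     pixel_size_nm)))
  next_label <- 0L
  for (ci in seq_len(n_comp)) {
    idx <- which(comp == ci, arr.ind = TRUE)
    r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
    c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
    # pad by 1 so the distance transform sees background all round
    sub <- matrix(FALSE, r1 - r0 + 3L, c1 - c0 + 3L)
    sub[cbind(idx[, 1L] - r0 + 2L, idx[, 2L] - c0 + 2L)] <- TRUE
    labs <- split_component(sub, sep_px)
    pos <- cbind(idx[, 1L], idx[, 2L])
    sub_lab <- labs[cbind(idx[, 1L] - r0 + 2L, idx[, 2L] - c0 + 2L)]
    out[pos] <- next_label + sub_lab
    next_label <- next_label + max(sub_lab)
  }
  label_map(out, pixel_size_nm)
}

# Seeded watershed inside one connected component (logical matrix,
# padded). Returns an integer matrix with labels 1..k on the component.
split_component <- function(sub, sep_px) {
  dm <- EBImage::distmap(sub * 1)
  dms <- if (min(dim(sub)) >= 9L) EBImage::gblur(dm, sigma = 1.5) else dm
  mx <- max_filter(dms, sep_px)
  seeds_mask <- sub & (dms > mx - 0.5)
  seeds <- EBImage::bwlabel(seeds_mask * 1)
  storage.mode(seeds) <- "integer"
  if (max(seeds) <= 1L)
    return(matrix(as.integer(sub), nrow(sub)))
  ws <- EBImage::propagate(x = max(dm) - dm, seeds = seeds,
                           mask = sub, lambda = 1e-4)
  ws <- matrix(as.integer(ws), nrow(sub))
  # guard against seeds swallowed by propagate edge cases
  ws[sub & ws == 0L] <- max(ws) + 1L
  relab <- match(ws[sub], sort(unique(ws[sub])))
  outm <- matrix(0L, nrow(sub), ncol(sub))
  outm[sub] <- relab
  outm
}

# Square running-max filter of radius r (window 2r+1), separable with
# logarithmic shift-doubling along each axis.
max_filter <- function(x, r) {
  x <- running_max_axis(x, r, rows = TRUE)
  running_max_axis(x, r, rows = FALSE)
}

# One-axis max over offsets -r..r via forward/backward doubling.
running_max_axis <- function(x, r, rows) {
  shift <- function(m, d) {   # shift down/right by d (rows/cols axis)
    n <- if (rows) nrow(m) else ncol(m)
    if (d >= n) return(matrix(-Inf, nrow(m), ncol(m)))
    if (rows) rbind(matrix(-Inf, d, ncol(m)),
                    m[seq_len(n - d), , drop = FALSE])
    else cbind(matrix(-Inf, nrow(m), d),
               m[, seq_len(n - d), drop = FALSE])
  }
  one_side <- function(m, r) {          # max over offsets 0..r
    y <- m; covered <- 1L
    while (covered <= r) {
      step <- min(covered, r - covered + 1L)
      y <- pmax(y, shift(y, step))
      covered <- covered + step
    }
    y
  }
  fwd <- one_side(x, r)
  # backward: reverse the axis, run forward, reverse again
  rev_axis <- function(m) if (rows) m[rev(seq_len(nrow(m))), , drop = FALSE]
                          else m[, rev(seq_len(ncol(m))), drop = FALSE]
  bwd <- rev_axis(one_side(rev_axis(x), r))
  pmax(fwd, bwd)
}

#' Area and minor-axis filtering of labelled objects
#'
#' Eliminates every object whose area is below `min_area_nm2` or whose
#' moment-based minor-axis length exceeds `max_minor_axis_nm`, then
#' relabels the survivors consecutively. The area rule removes debris
#' too small to be a rod; the minor-axis rule removes wide clumps that
#' cannot be a single rod of ~18 nm width.
#'
#' @param labels a [label_map].
#' @param params a [segmentation_params].
#' @return A filtered [label_map].
#' @export
filter_objects <- function(labels, params = segmentation_params()) {
  stopifnot(inherits(labels, "label_map"))
  if (labels$n_objects == 0L) return(labels)
  px <- labels$pixel_size_nm
  keep <- logical(labels$n_objects)
  for (k in seq_len(labels$n_objects)) {
    idx <- which(labels$labels == k, arr.ind = TRUE)
    area_nm2 <- px_to_nm(nrow(idx), px, "area")
    minor_nm <- minor_axis_px(idx) * px
    keep[k] <- area_nm2 >= params$min_area_nm2 &&
      minor_nm <= params$max_minor_axis_nm
  }
  new_lab <- matrix(0L, nrow(labels$labels), ncol(labels$labels))
  relab <- cumsum(keep)
  sel <- labels$labels > 0L
  old <- labels$labels[sel]
  new_lab[sel] <- ifelse(keep[old], relab[old], 0L)
  label_map(new_lab, px)
}

# Minor axis (px) of the ellipse with the same normalized second central
# moments as the pixel-centre point set (regionprops convention).
minor_axis_px <- function(idx) {
  if (nrow(idx) < 2L) return(0)
  mu <- colMeans(idx)
  d <- sweep(idx, 2L, mu)
  c20 <- mean(d[, 1L]^2); c02 <- mean(d[, 2L]^2); c11 <- mean(d[, 1L] * d[, 2L])
  lam_min <- (c20 + c02) / 2 - sqrt(((c20 - c02) / 2)^2 + c11^2)
  4 * sqrt(max(lam_min, 0))
}

major_axis_px <- function(idx) {
  if (nrow(idx) < 2L) return(0)
  mu <- colMeans(idx)
  d <- sweep(idx, 2L, mu)
  c20 <- mean(d[, 1L]^2); c02 <- mean(d[, 2L]^2); c11 <- mean(d[, 1L] * d[, 2L])
  lam_max <- (c20 + c02) / 2 + sqrt(((c20 - c02) / 2)^2 + c11^2)
  4 * sqrt(max(lam_max, 0))
}

#' Full segmentation pipeline
#'
#' Runs [binarize_adaptive()], [morphological_cleanup()],
#' [watershed_split()] and [filter_objects()] in sequence.
#'
#' @param img a [micrograph].
#' @param params a [segmentation_params].
#' @return A [label_map] of accepted candidate rods.
#' @examples
#' \donttest{
#' sc <- render_scene(scene_params(n_rods = 3, image_size_px = 512,
#'                                 rod_length_nm = 49), seed = 1)
#' seg <- segment_micrograph(sc$image)
#' seg$n_objects
#' }
#' @export
segment_micrograph <- function(img, params = segmentation_params()) {
  mask <- binarize_adaptive(img, params)
  mask <- morphological_cleanup(mask, params)
  labs <- watershed_split(mask, img$pixel_size_nm, params)
  filter_objects(labs, params)
}
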