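# Synthetic negative-stain micrographs of nanorods with full ground truth.

#' Synthetic scene parameters
#'
#' Describes a negative-stain-like micrograph: dark capsule-shaped rods
#' (a rectangle with semicircular end caps, the projection of a
#' cylindrical rod) on a brighter, noisy background with an optional
#' smooth illumination gradient. Intensities are kept in \[0, 1\] so
#' scenes can be written as float TIFF. Defaults emulate the published
#' acquisition geometry (0.3482 nm/px, 18 nm rod width) at a 1024 px
#' frame for fast tests; use `image_size_px = 4096` for full-frame
#' scenes.
#'
#' @param image_size_px frame edge length in px (square image).
#' @param pixel_size_nm pixel calibration in nm.
#' @param n_rods number of isolated rods to place at random positions
#'   and orientations.
#' @param rod_length_nm true tip-to-tip rod length(s) in nm; a vector is
#'   sampled uniformly per rod.
#' @param rod_width_nm true rod width in nm.
#' @param n_pairs_end_to_end rods aggregated end to end with zero gap:
#'   rendered as a single merged capsule of twice the unit length,
#'   recorded with `multimer_k = 2`.
#' @param n_pairs_side_by_side "rogue" pairs: two parallel rods lying
#'   `side_pair_gap_nm` apart, recorded as kind `side_by_side_pair`.
#'   The cleanup dilations bridge the small gap into one component with
#'   a concave waist, the situation watershed is meant to resolve; with
#'   `side_pair_gap_nm = 0` the rods are tangent and merge into a solid
#'   footprint that cannot be split (the classic rogue object).
#' @param n_debris roundish non-rod blobs (random ellipses, 4-30 nm
#'   semi-axes).
#' @param background_level mean background intensity.
#' @param object_contrast how much darker a rod is than the background.
#' @param gaussian_sd additive Gaussian noise SD (default 10% of the
#'   object contrast).
#' @param gradient_amplitude peak-to-peak amplitude of a planar
#'   illumination ramp in a random direction.
#' @param min_gap_nm minimum clearance between distinct objects'
#'   footprints, so "isolated" rods stay separate even after the
#'   pipeline's dilations.
#' @param margin_px placement margin from the frame border.
#' @param max_place_tries rejection-sampling attempts per object before
#'   a placement error is raised.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(image_size_px = 1024L,
                         pixel_size_nm = DEFAULT_PIXEL_SIZE_NM,
                         n_rods = 10L,
                         rod_length_nm = 49,
                         rod_width_nm = 18,
                         n_pairs_end_to_end = 0L,
                         n_pairs_side_by_side = 0L,
                         side_pair_gap_nm = 2,
                         n_debris = 0L,
                         background_level = 0.70,
                         object_contrast = 0.35,
                         gaussian_sd = 0.035,
                         gradient_amplitude = 0.03,
                         min_gap_nm = 15,
                         margin_px = 10L,
                         max_place_tries = 2000L) {
  stopifnot(image_size_px >= 64L, pixel_size_nm > 0,
            all(rod_length_nm >= rod_width_nm), rod_width_nm > 0,
            gaussian_sd >= 0, min_gap_nm >= 0)
  structure(as.list(environment()), class = "scene_params")
}

#' Render a synthetic micrograph with ground truth
#'
#' Deterministic for a fixed seed (the caller's RNG state is left
#' untouched). Rods are placed by rejection sampling so that distinct
#' objects keep at least `min_gap_nm` clearance; if the requested
#' objects cannot fit, a placement error is raised. The final image is
#' rounded to 32-bit float precision so that writing to float TIFF/MRC
#' and reloading reproduces it bit-exactly.
#'
#' @param params a [scene_params].
#' @param seed integer RNG seed.
#' @param rods optional data.frame of explicit rods (columns
#'   `center_row_px`, `center_col_px`, `orientation_deg`, `length_nm`,
#'   `width_nm`, optional `multimer_k`), bypassing random placement --
#'   e.g. to test border truncation. Explicit rods are not checked
#'   against the frame bounds.
#' @return A `synthetic_scene`: list with `image` (a [micrograph]),
#'   `rods` (ground-truth table: `rod_id`, `kind`, `true_length_nm`,
#'   `true_width_nm`, `orientation_deg`, `center_row_px`,
#'   `center_col_px`, `multimer_k`), `debris`, `noise_model`, `seed`.
#' @examples
#' sc <- render_scene(scene_params(n_rods = 3, image_size_px = 512),
#'                    seed = 7)
#' sc$rods$true_length_nm
#' @export
render_scene <- function(params = scene_params(), seed = 1L,
                         rods = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  p <- params
  n <- p$image_size_px
  px <- p$pixel_size_nm

  placed <- list()   # each: list(segs = list of 2x2 endpoint matrices, width_px)
  truth <- list()
  rid <- 0L

  seg_for <- function(center, theta_deg, length_nm, width_nm) {
    half <- (length_nm - width_nm) / 2 / px
    th <- theta_deg * pi / 180
    d <- c(-sin(th), cos(th))      # (row, col) direction
    rbind(center - half * d, center + half * d)
  }

  place_object <- function(segs, width_px, gap_px) {
    for (pl in placed) {
      for (s1 in segs) for (s2 in pl$segs) {
        if (segment_distance(s1, s2) <
            (width_px + pl$width_px) / 2 + gap_px)
          return(FALSE)
      }
    }
    TRUE
  }

  sample_one <- function(length_nm, width_nm, kind, k,
                         extra_width_px = 0, record = TRUE) {
    wpx <- width_nm / px
    gap_px <- p$min_gap_nm / px
    half_ext <- (length_nm / 2) / px + extra_width_px
    lo <- p$margin_px + half_ext
    hi <- n - p$margin_px - half_ext
    if (hi <= lo)
      stop("object of length ", length_nm,
           " nm cannot fit in the frame", call. = FALSE)
    for (try in seq_len(p$max_place_tries)) {
      center <- c(runif(1, lo, hi), runif(1, lo, hi))
      theta <- runif(1, 0, 180)
      segs <- list(seg_for(center, theta, length_nm, width_nm))
      if (kind == "side_by_side_pair") {
        th <- theta * pi / 180
        off <- ((width_nm + p$side_pair_gap_nm) / px) *
          c(cos(th), sin(th))                         # perpendicular
        segs <- list(seg_for(center - off / 2, theta, length_nm, width_nm),
                     seg_for(center + off / 2, theta, length_nm, width_nm))
      }
      if (place_object(segs, wpx + 2 * extra_width_px, gap_px)) {
        placed[[length(placed) + 1L]] <<- list(segs = segs,
                                               width_px = wpx)
        if (record) {
          rid <<- rid + 1L
          truth[[length(truth) + 1L]] <<- data.frame(
            rod_id = rid, kind = kind, true_length_nm = length_nm,
            true_width_nm = width_nm, orientation_deg = theta,
            center_row_px = center[1L], center_col_px = center[2L],
            multimer_k = k, stringsAsFactors = FALSE)
        }
        return(segs)
      }
    }
    stop("placement failed after ", p$max_place_tries,
         " tries; reduce object count or size", call. = FALSE)
  }

  # --- background -----------------------------------------------------
  phi <- runif(1, 0, 2 * pi)
  rr <- (row(matrix(0, n, n)) - n / 2) / n
  cc <- (col(matrix(0, n, n)) - n / 2) / n
  img <- p$background_level +
    p$gradient_amplitude * (rr * cos(phi) + cc * sin(phi))

  draw_capsule <- function(img, segs, width_nm, contrast) {
    wpx2 <- width_nm / px / 2
    for (s in segs) {
      r0 <- max(1L, floor(min(s[, 1L]) - wpx2 - 2))
      r1 <- min(n, ceiling(max(s[, 1L]) + wpx2 + 2))
      c0 <- max(1L, floor(min(s[, 2L]) - wpx2 - 2))
      c1 <- min(n, ceiling(max(s[, 2L]) + wpx2 + 2))
      if (r1 < r0 || c1 < c0) next
      pr <- seq(r0, r1) - 0.5
      pc <- seq(c0, c1) - 0.5
      d <- point_segment_dist_grid(pr, pc, s)
      cover <- pmin(pmax(wpx2 - d + 0.5, 0), 1)   # 1-px soft edge
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] - contrast * cover
    }
    img
  }

  # --- rods -----------------------------------------------------------
  all_segs <- list()
  seg_widths <- numeric(0)
  seg_contrast <- numeric(0)
  add_segs <- function(segs, width_nm, contrast) {
    all_segs <<- c(all_segs, segs)
    seg_widths <<- c(seg_widths, rep(width_nm, length(segs)))
    seg_contrast <<- c(seg_contrast, rep(contrast, length(segs)))
  }
  debris <- list()
  if (is.null(rods)) {
    lens <- if (length(p$rod_length_nm) > 1L)
      sample(p$rod_length_nm, p$n_rods, replace = TRUE)
    else rep(p$rod_length_nm, p$n_rods)
    for (L in lens)
      add_segs(sample_one(L, p$rod_width_nm, "rod", 1L),
               p$rod_width_nm, p$object_contrast)
    for (i in seq_len(p$n_pairs_end_to_end))
      add_segs(sample_one(2 * p$rod_length_nm[1L], p$rod_width_nm,
                          "end_to_end_pair", 2L),
               p$rod_width_nm, p$object_contrast)
    for (i in seq_len(p$n_pairs_side_by_side))
      add_segs(sample_one(p$rod_length_nm[1L], p$rod_width_nm,
                          "side_by_side_pair", 1L,
                          extra_width_px = p$rod_width_nm / px / 2),
               p$rod_width_nm, p$object_contrast)
    for (i in seq_len(p$n_debris)) {
      a_nm <- runif(1, 4, 30); b_nm <- runif(1, 4, min(a_nm, 20))
      Lb <- max(2 * a_nm, 2 * b_nm + 0.1)
      dseg <- sample_one(Lb, 2 * b_nm, "debris", 1L, record = FALSE)
      debris[[length(debris) + 1L]] <- list(length_nm = Lb,
                                            width_nm = 2 * b_nm)
      add_segs(dseg, 2 * b_nm, p$object_contrast * runif(1, 0.5, 1))
    }
  } else {
    for (i in seq_len(nrow(rods))) {
      rid <- rid + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        rod_id = rid, kind = "rod",
        true_length_nm = rods$length_nm[i],
        true_width_nm = rods$width_nm[i],
        orientation_deg = rods$orientation_deg[i],
        center_row_px = rods$center_row_px[i],
        center_col_px = rods$center_col_px[i],
        multimer_k = if ("multimer_k" %in% names(rods))
          rods$multimer_k[i] else 1L,
        stringsAsFactors = FALSE)
      add_segs(list(seg_for(
        c(rods$center_row_px[i], rods$center_col_px[i]),
        rods$orientation_deg[i], rods$length_nm[i], rods$width_nm[i])),
        rods$width_nm[i], p$object_contrast)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(rod_id = integer(), kind = character(),
               true_length_nm = numeric(), true_width_nm = numeric(),
               orientation_deg = numeric(), center_row_px = numeric(),
               center_col_px = numeric(), multimer_k = integer(),
               stringsAsFactors = FALSE)

  for (i in seq_along(all_segs))
    img <- draw_capsule(img, all_segs[i], seg_widths[i],
                        seg_contrast[i])

  # --- noise, clamp, float32 snap ------------------------------------
  if (p$gaussian_sd > 0)
    img <- img + matrix(rnorm(n * n, 0, p$gaussian_sd), n, n)
  img <- pmin(pmax(img, 0), 1)
  img <- snap_float32(img)

  scene_id <- sprintf("synthetic:seed=%d:n=%d", seed, nrow(truth_df))
  structure(list(
    image = micrograph(img, pixel_size_nm = px, source_id = scene_id),
    rods = truth_df,
    debris = debris,
    noise_model = list(background_level = p$background_level,
                       object_contrast = p$object_contrast,
                       gaussian_sd = p$gaussian_sd,
                       gradient_amplitude = p$gradient_amplitude),
    params = p,
    segments = all_segs, segment_widths = seg_widths,
    seed = seed), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d rod object(s), %d debris, seed %d\n",
              nrow(x$rods), length(x$debris), x$seed))
  print(x$image)
  invisible(x)
}

# Round doubles to float32 representability (so float TIFF/MRC round-trip
# is bit-exact).
snap_float32 <- function(x) {
  v <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
               size = 4L, n = length(x))
  matrix(v, nrow(x))
}

#' Exact ground-truth object mask of a scene
#'
#' @param scene a `synthetic_scene`.
#' @return Logical matrix: `TRUE` inside any rendered rod/debris
#'   footprint (hard, unsoftened outline).
#' @export
scene_truth_mask <- function(scene) {
  n <- nrow(scene$image$pixels)
  px <- scene$image$pixel_size_nm
  mask <- matrix(FALSE, n, n)
  for (i in seq_along(scene$segments)) {
    s <- scene$segments[[i]]
    wpx2 <- scene$segment_widths[i] / px / 2
    r0 <- max(1L, floor(min(s[, 1L]) - wpx2 - 1))
    r1 <- min(n, ceiling(max(s[, 1L]) + wpx2 + 1))
    c0 <- max(1L, floor(min(s[, 2L]) - wpx2 - 1))
    c1 <- min(n, ceiling(max(s[, 2L]) + wpx2 + 1))
    if (r1 < r0 || c1 < c0) next
    d <- point_segment_dist_grid(seq(r0, r1) - 0.5, seq(c0, c1) - 0.5, s)
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (d <= wpx2)
  }
  mask
}

#' Ground-truth length report of a scene
#'
#' The report the measurement pipeline should ideally produce: the true
#' object lengths (end-to-end pairs contribute their merged length)
#' binned exactly like [build_report()].
#'
#' @param scene a `synthetic_scene`.
#' @param bin_width_nm histogram bin width in nm.
#' @return A `length_report`.
#' @export
scene_ground_truth_report <- function(scene, bin_width_nm = 10) {
  if (nrow(scene$rods) == 0L)
    return(build_report(empty_measurements(), bin_width_nm = bin_width_nm))
  m <- data.frame(source_id = scene$image$source_id,
                  object_id = scene$rods$rod_id,
                  length_nm = scene$rods$true_length_nm,
                  truncated = FALSE, excluded = FALSE,
                  stringsAsFactors = FALSE)
  build_report(m, bin_width_nm = bin_width_nm)
}

# Distance from every grid point (pr x pc, pixel-centre coordinates) to
# segment s (2x2 matrix of endpoints, rows = points).
point_segment_dist_grid <- function(pr, pc, s) {
  a <- s[1L, ]; b <- s[2L, ]
  ab <- b - a
  len2 <- sum(ab^2)
  R <- outer(pr - a[1L], rep(1, length(pc)))
  C <- outer(rep(1, length(pr)), pc - a[2L])
  if (len2 == 0) return(sqrt(R^2 + C^2))
  t <- (R * ab[1L] + C * ab[2L]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((R - t * ab[1L])^2 + (C - t * ab[2L])^2)
}

# Minimum distance between two segments (2x2 endpoint matrices).
segment_distance <- function(s1, s2) {
  if (segments_intersect(s1, s2)) return(0)
  min(point_seg_dist(s1[1L, ], s2), point_seg_dist(s1[2L, ], s2),
      point_seg_dist(s2[1L, ], s1), point_seg_dist(s2[2L, ], s1))
}

point_seg_dist <- function(pt, s) {
  a <- s[1L, ]; b <- s[2L, ]
  ab <- b - a; len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((pt - a)^2)))
  t <- pmin(pmax(sum((pt - a) * ab) / len2, 0), 1)
  sqrt(sum((pt - a - t * ab)^2))
}

segments_intersect <- function(s1, s2) {
  o <- function(p, q, r)
    sign((q[1L] - p[1L]) * (r[2L] - p[2L]) -
         (q[2L] - p[2L]) * (r[1L] - p[1L]))
  o1 <- o(s1[1L, ], s1[2L, ], s2[1L, ])
  o2 <- o(s1[1L, ], s1[2L, ], s2[2L, ])
  o3 <- o(s2[1L, ], s2[2L, ], s1[1L, ])
  o4 <- o(s2[1L, ], s2[2L, ], s1[2L, ])
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && o2 == 0 && o3 == 0 && o4 == 0 &&
     !(max(s1[, 1L]) < min(s2[, 1L]) || max(s2[, 1L]) < min(s1[, 1L]) ||
       max(s1[, 2L]) < min(s2[, 2L]) || max(s2[, 2L]) < min(s1[, 2L])))
}
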