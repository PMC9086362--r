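# End-to-end runs over one or more micrographs, with a declarative
# run configuration that round-trips through YAML.

#' Run configuration
#'
#' Bundles every tunable of a measurement run: segmentation and
#' measurement parameters, histogram bin width, truncated-rod policy,
#' pooling, and the RNG seed echoed into the run manifest.
#'
#' @param segmentation a [segmentation_params].
#' @param measurement a [measurement_params].
#' @param bin_width_nm report bin width in nm.
#' @param include_truncated include border-touching rods in reports?
#' @param pool also write a pooled report across all input images?
#' @param pixel_size_override optional nm/px used for files without
#'   calibration metadata.
#' @param seed integer seed recorded in the manifest (the measurement
#'   pipeline itself is deterministic; the seed matters for synthetic
#'   input generation).
#' @return A list of class `run_config`.
#' @export
run_config <- function(segmentation = segmentation_params(),
                       measurement = measurement_params(),
                       bin_width_nm = 10,
                       include_truncated = FALSE,
                       pool = TRUE,
                       pixel_size_override = NULL,
                       seed = 1L) {
  structure(list(segmentation = segmentation,
                 measurement = measurement,
                 bin_width_nm = bin_width_nm,
                 include_truncated = include_truncated,
                 pool = pool,
                 pixel_size_override = pixel_size_override,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The file round-trips losslessly: `read_run_config(write_run_config(x))`
#' reproduces `x`.
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @return `path` (write) or a [run_config] (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- list(segmentation = unclass(config$segmentation),
               measurement = unclass(config$measurement),
               bin_width_nm = config$bin_width_nm,
               include_truncated = config$include_truncated,
               pool = config$pool,
               pixel_size_override = config$pixel_size_override,
               seed = config$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    segmentation = do.call(segmentation_params, y$segmentation),
    measurement = do.call(measurement_params, y$measurement),
    bin_width_nm = y$bin_width_nm,
    include_truncated = y$include_truncated,
    pool = y$pool,
    pixel_size_override = y$pixel_size_override,
    seed = y$seed)
}

#' Measure nanorods across a set of micrographs
#'
#' Runs the full pipeline (adaptive threshold, morphological cleanup,
#' watershed, filters, Feret measurement, Pythagorean length) on each
#' image, writes one measurement CSV per image plus report CSVs, and --
#' when `config$pool` is `TRUE` -- a pooled measurement CSV and report
#' across all images. A YAML run manifest with the full parameter set
#' and package version is written alongside. Output ordering is fixed
#' (images in input order, objects by label), so identical inputs and
#' configuration give byte-identical CSVs.
#'
#' @param images character vector of image paths, or a list of
#'   [micrograph] objects (e.g. from [render_scene()]).
#' @param out_dir output directory, created if needed.
#' @param config a [run_config].
#' @return Invisibly, a list with `measurements` (pooled data.frame),
#'   `per_image` (list of data.frames), `report` (pooled
#'   `length_report`, or `NULL` when pooling is off) and `failed`
#'   (character vector of unreadable inputs).
#' @export
run_measure <- function(images, out_dir, config = run_config()) {
  if (length(images) == 0L)
    stop("no input images given", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_image <- list()
  failed <- character(0)
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (inherits(im, "micrograph")) {
      mg <- im
      stem <- sprintf("image_%03d", i)
    } else {
      stem <- sub("\\.[^.]*$", "", basename(im))
      mg <- tryCatch(
        load_micrograph(im,
                        pixel_size_override = config$pixel_size_override),
        error = function(e) {
          message("skipping unreadable input ", im, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(mg)) { failed <- c(failed, im); next }
    }
    labs <- segment_micrograph(mg, config$segmentation)
    meas <- measure_rods(labs, config$measurement,
                         source_id = mg$source_id)
    write_measurements(meas, file.path(out_dir,
                                       paste0(stem, "_measurements.csv")))
    write_report(build_report(meas, config$bin_width_nm,
                              config$include_truncated),
                 file.path(out_dir, paste0(stem, "_report")))
    per_image[[stem]] <- meas
  }
  pooled <- if (length(per_image)) do.call(rbind, per_image)
            else empty_measurements()
  rownames(pooled) <- NULL
  report <- NULL
  if (isTRUE(config$pool)) {
    write_measurements(pooled, file.path(out_dir,
                                         "pooled_measurements.csv"))
    report <- build_report(pooled, config$bin_width_nm,
                           config$include_truncated)
    write_report(report, file.path(out_dir, "pooled_report"))
  }
  manifest <- file.path(out_dir, "run_manifest.yaml")
  yaml::write_yaml(list(
    package = "nanorodem",
    version = as.character(utils::packageVersion("nanorodem")),
    n_images = length(images), n_failed = length(failed),
    config = yaml::yaml.load(yaml::as.yaml(list(
      segmentation = unclass(config$segmentation),
      measurement = unclass(config$measurement),
      bin_width_nm = config$bin_width_nm,
      include_truncated = config$include_truncated,
      pool = config$pool, seed = config$seed)))), manifest)
  invisible(list(measurements = pooled, per_image = per_image,
                 report = report, failed = failed))
}
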