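# Reporting: 10-nm binned length histograms, descriptive statistics,
# manual exclusion of mis-segmented ("rogue") records, multimer classing.

#' Build a length-distribution report
#'
#' Bins included rod lengths into fixed-width, zero-anchored,
#' left-closed bins (default `[0,10), [10,20), ...` nm) and computes
#' descriptive statistics (mean, median, sample SD, min, max, count).
#' Records are omitted when `excluded` is `TRUE`, when the length is
#' undefined (Feret below the rod width), or -- by default -- when the
#' object touches the image border, since such lengths are only lower
#' bounds.
#'
#' @param measurements measurement data.frame from [measure_rods()].
#' @param bin_width_nm histogram bin width in nm (> 0); the published
#'   convention is 10 nm increments.
#' @param include_truncated keep border-touching rods?
#' @return A `length_report`: list with `bin_edges`, `counts`, `stats`
#'   (list with `mean`, `median`, `sd`, `min`, `max`, `count`),
#'   `n_excluded` and `bin_width_nm`. With no usable lengths the stats
#'   are `NA` and `counts` is empty.
#' @examples
#' m <- data.frame(source_id = "x", object_id = 1:3,
#'                 length_nm = c(49, 49, 257),
#'                 truncated = FALSE, excluded = FALSE)
#' r <- build_report(m)
#' r$stats$mean  # 118.33
#' @export
build_report <- function(measurements, bin_width_nm = 10,
                         include_truncated = FALSE) {
  if (bin_width_nm <= 0)
    stop("`bin_width_nm` must be > 0", call. = FALSE)
  n_excluded <- sum(measurements$excluded)
  keep <- !measurements$excluded & !is.na(measurements$length_nm)
  if (!include_truncated) keep <- keep & !measurements$truncated
  lens <- measurements$length_nm[keep]
  if (length(lens) == 0L) {
    return(structure(list(
      bin_edges = numeric(0), counts = integer(0),
      stats = list(mean = NA_real_, median = NA_real_, sd = NA_real_,
                   min = NA_real_, max = NA_real_, count = 0L),
      n_excluded = n_excluded, bin_width_nm = bin_width_nm,
      empty = TRUE), class = "length_report"))
  }
  n_bins <- floor(max(lens) / bin_width_nm) + 1L
  edges <- seq(0, by = bin_width_nm, length.out = n_bins + 1L)
  counts <- tabulate(floor(lens / bin_width_nm) + 1L, nbins = n_bins)
  structure(list(
    bin_edges = edges, counts = counts,
    stats = list(mean = mean(lens), median = median(lens),
                 sd = if (length(lens) > 1L) sd(lens) else NA_real_,
                 min = min(lens), max = max(lens),
                 count = length(lens)),
    n_excluded = n_excluded, bin_width_nm = bin_width_nm,
    empty = FALSE), class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  if (x$empty) {
    cat("length_report: no usable measurements",
        sprintf("(%d excluded)\n", x$n_excluded))
    return(invisible(x))
  }
  s <- x$stats
  cat(sprintf(paste0("length_report: n = %d rods (%d excluded), ",
                     "%g nm bins\n"), s$count, x$n_excluded,
              x$bin_width_nm))
  cat(sprintf("  mean %.2f  median %.2f  sd %.2f  min %.2f  max %.2f nm\n",
              s$mean, s$median, s$sd, s$min, s$max))
  occ <- which(x$counts > 0)
  for (i in occ)
    cat(sprintf("  [%4g, %4g) nm : %d\n", x$bin_edges[i],
                x$bin_edges[i + 1L], x$counts[i]))
  invisible(x)
}

#' Plot a length histogram
#'
#' @param x a `length_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.length_report <- function(x, ...) {
  if (x$empty) stop("empty report", call. = FALSE)
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  barplot(x$counts, names.arg = sprintf("%g", mids), space = 0,
          xlab = "length (nm)", ylab = "number of nanorods", ...)
  invisible(x)
}

#' Write report tables to CSV
#'
#' Writes a per-bin table (`<stem>_bins.csv`) and a one-row statistics
#' table (`<stem>_stats.csv`).
#'
#' @param report a `length_report`.
#' @param stem output path stem (no extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(report, stem) {
  bins_path <- paste0(stem, "_bins.csv")
  stats_path <- paste0(stem, "_stats.csv")
  if (report$empty) {
    bins <- data.frame(bin_start_nm = numeric(), bin_end_nm = numeric(),
                       count = integer())
  } else {
    bins <- data.frame(
      bin_start_nm = report$bin_edges[-length(report$bin_edges)],
      bin_end_nm = report$bin_edges[-1],
      count = report$counts)
  }
  write.csv(bins, bins_path, row.names = FALSE, quote = FALSE)
  s <- report$stats
  write.csv(data.frame(mean_nm = s$mean, median_nm = s$median,
                       sd_nm = s$sd, min_nm = s$min, max_nm = s$max,
                       count = s$count, n_excluded = report$n_excluded),
            stats_path, row.names = FALSE, quote = FALSE)
  invisible(c(bins_path, stats_path))
}

#' Flag rogue measurements for exclusion
#'
#' Mis-segmented objects -- typically two rods joined side-by-side --
#' can be discarded manually. Matching records get `excluded = TRUE`;
#' nothing is deleted, so the audit trail (and every measured value)
#' is preserved. Unknown ids produce a warning, not an error. The
#' operation is idempotent.
#'
#' @param measurements measurement data.frame.
#' @param ids data.frame with columns `source_id` and `object_id`.
#' @return The measurement data.frame with updated `excluded` flags.
#' @export
exclude_rogue <- function(measurements, ids) {
  stopifnot(is.data.frame(ids), all(c("source_id", "object_id") %in%
                                    names(ids)))
  key <- paste(measurements$source_id, measurements$object_id, sep = "\r")
  want <- paste(ids$source_id, ids$object_id, sep = "\r")
  unknown <- setdiff(want, key)
  if (length(unknown))
    warning(length(unknown), " exclusion id(s) match no record; ignored")
  measurements$excluded <- measurements$excluded | key %in% want
  measurements
}

#' Classify rods into end-to-end multimer classes
#'
#' Rods aggregate end to end, so a population built on one RNA of unit
#' length U shows lengths near U, 2U, 3U, ... Each included rod is
#' assigned the nearest multiple `k = round(L / U)` (half-multiples
#' round up; `k = 0` is coerced to 1 and flagged) with the residual
#' `L - k * U`.
#'
#' @param measurements measurement data.frame.
#' @param unit_length_nm monomer length U in nm (> 0).
#' @return A data.frame with `source_id`, `object_id`, `length_nm`, `k`,
#'   `residual_nm`, `coerced`; attribute `unit_length_nm`.
#' @examples
#' m <- data.frame(source_id = "x", object_id = 1:2,
#'                 length_nm = c(98, 120), truncated = FALSE,
#'                 excluded = FALSE)
#' classify_multimers(m, 49)$k  # 2 2
#' @export
classify_multimers <- function(measurements, unit_length_nm) {
  if (unit_length_nm <= 0)
    stop("`unit_length_nm` must be > 0", call. = FALSE)
  keep <- !measurements$excluded & !is.na(measurements$length_nm)
  m <- measurements[keep, , drop = FALSE]
  # round-half-up (base round() is banker's rounding)
  k <- floor(m$length_nm / unit_length_nm + 0.5)
  coerced <- k < 1
  k[coerced] <- 1
  out <- data.frame(source_id = m$source_id, object_id = m$object_id,
                    length_nm = m$length_nm, k = as.integer(k),
                    residual_nm = m$length_nm - k * unit_length_nm,
                    coerced = coerced, stringsAsFactors = FALSE)
  attr(out, "unit_length_nm") <- unit_length_nm
  out
}
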