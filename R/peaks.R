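#' Noise filter for fragmentation spectra
#'
#' A peak is retained when its intensity is at least
#' `max(relative_threshold * base-peak intensity, absolute_floor)` and its
#' m/z lies inside the optional window. The defaults (1% of base peak, no
#' absolute floor, full window) are the package's own operating point; the
#' filter used is recorded in every [filter_peaks()] result for
#' provenance.
#'
#' @param relative_threshold fraction of the base-peak intensity, in
#'   `[0, 1)`.
#' @param absolute_floor absolute intensity floor (arbitrary units).
#' @param min_mz,max_mz optional m/z window.
#' @return a `noise_filter` list.
#' @export
noise_filter <- function(relative_threshold = 0.01, absolute_floor = 0,
                         min_mz = NULL, max_mz = NULL) {
  stopifnot(relative_threshold >= 0, relative_threshold < 1,
            absolute_floor >= 0)
  structure(list(relative_threshold = relative_threshold,
                 absolute_floor = absolute_floor,
                 min_mz = min_mz, max_mz = max_mz),
            class = "noise_filter")
}

#' Filter noise peaks and count what survives
#'
#' @param s an `ms_spectrum`.
#' @param f a [noise_filter()].
#' @return a `peak_count` list: `scan_id`, `raw_peaks`, `filtered_peaks`
#'   (`<= raw_peaks`), `filter_params`, and `spectrum`, the filtered
#'   spectrum (so that filtering is idempotent by construction: the base
#'   peak always survives, hence a second pass sees the same threshold).
#' @export
filter_peaks <- function(s, f = noise_filter()) {
  stopifnot(inherits(s, "ms_spectrum"), inherits(f, "noise_filter"))
  pk <- s$peaks
  raw <- nrow(pk)
  if (raw > 0L) {
    thr <- max(f$relative_threshold * max(pk$intensity), f$absolute_floor)
    keep <- pk$intensity >= thr
    if (!is.null(f$min_mz)) keep <- keep & pk$mz >= f$min_mz
    if (!is.null(f$max_mz)) keep <- keep & pk$mz <= f$max_mz
    pk <- pk[keep, , drop = FALSE]
  }
  filtered <- spectrum(pk$mz, pk$intensity, ms_level = s$ms_level,
                       precursor_mz = if (s$ms_level == 2L) s$precursor_mz else NULL,
                       retention_time = s$retention_time, scan_id = s$scan_id)
  structure(list(scan_id = s$scan_id, raw_peaks = raw,
                 filtered_peaks = nrow(pk), filter_params = f,
                 spectrum = filtered),
            class = "peak_count")
}

#' @export
print.peak_count <- function(x, ...) {
  cat(sprintf("<peak_count> scan %s: %d of %d peaks above noise\n",
              x$scan_id, x$filtered_peaks, x$raw_peaks))
  invisible(x)
}

#' Averaged filtered peak count for a calibration standard
#'
#' Standards are acquired as repeated targeted (SIM + MS2) scans of one
#' known molecule; replicate MS2 scans whose precursor matches the target
#' mass are filtered and their peak counts averaged (arithmetic mean,
#' unrounded) before regression.
#'
#' @param spectra list of `ms_spectrum`.
#' @param target_mz the standard's ion m/z.
#' @param tolerance precursor match tolerance in Th (default 0.25, half
#'   the 0.5-Da isolation window).
#' @param f a [noise_filter()].
#' @return mean filtered peak count (numeric scalar).
#' @export
count_for_standard <- function(spectra, target_mz, tolerance = 0.25,
                               f = noise_filter()) {
  ms2 <- Filter(function(s) inherits(s, "ms_spectrum") && s$ms_level == 2L &&
                  !is.na(s$precursor_mz) &&
                  abs(s$precursor_mz - target_mz) <= tolerance,
                spectra)
  if (length(ms2) == 0L)
    stop(sprintf("no MS2 scan with precursor within %g of m/z %g",
                 tolerance, target_mz))
  mean(vapply(ms2, function(s) filter_peaks(s, f)$filtered_peaks, 0L))
}
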