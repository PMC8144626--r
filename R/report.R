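#' Estimate the assembly index of every fragmented ion in a mixture run
#' and classify the sample
#'
#' The experimental biosignature readout: each MS2 scan in the run is
#' noise-filtered, its surviving peaks counted, and the count converted to
#' an MA estimate (median + 90% band) through the calibration model. The
#' sample's MA is the maximum of the per-ion median estimates, and the
#' verdict is `above_threshold` when that maximum exceeds `threshold`
#' (default 15, the value above which only samples containing molecules of
#' biological or technological origin scored). A verdict of
#' `below_threshold` means "no high-MA molecules detected", not "abiotic":
#' the assay is robust to false positives but not to false negatives.
#'
#' A warning is emitted when two distinct precursors in the run fall
#' within the MS2 isolation width (possible isomer/isobar co-isolation,
#' which inflates peak counts and is not corrected for).
#'
#' @param run list of `ms_spectrum`, or a path readable by
#'   [read_spectra()].
#' @param model a fitted [fit_calibration()] model.
#' @param filter a [noise_filter()].
#' @param threshold MA classification threshold (default 15).
#' @param sample_name label carried into the report.
#' @param isolation_width MS2 isolation width in Th used for the
#'   co-isolation warning (default 0.5).
#' @return a `sample_report`: `sample_name`, `ion_estimates` (data.frame),
#'   `max_ma`, `threshold`, `verdict` (`above_threshold`,
#'   `below_threshold`, or `NA` when the run had no usable MS2 scans, in
#'   which case `empty` is `TRUE`).
#' @export
analyze_sample <- function(run, model, filter = noise_filter(),
                           threshold = 15, sample_name = "sample",
                           isolation_width = 0.5) {
  if (is.character(run)) run <- read_spectra(run)
  if (!inherits(model, "ma_calibration"))
    stop("model must be a fitted ma_calibration (see fit_calibration)")
  ms2 <- Filter(function(s) inherits(s, "ms_spectrum") && s$ms_level == 2L,
                run)
  if (length(ms2) == 0L) {
    warning("no usable MS2 scans in run; report flagged empty")
    rep <- list(sample_name = sample_name,
                ion_estimates = data.frame(), max_ma = NA_real_,
                threshold = threshold, verdict = NA_character_,
                empty = TRUE)
    class(rep) <- "sample_report"
    return(rep)
  }
  prec <- sort(vapply(ms2, function(s) s$precursor_mz, 0))
  if (length(prec) > 1L) {
    d <- diff(unique(prec))
    if (length(d) && any(d < isolation_width))
      warning(sprintf("%d precursor pair(s) within the %.2f Th isolation width: possible co-isolation, peak counts may be inflated",
                      sum(d < isolation_width), isolation_width))
  }
  est <- do.call(rbind, lapply(ms2, function(s) {
    pc <- filter_peaks(s, filter)
    e <- estimate_ion(pc$filtered_peaks, model, precursor_mz = s$precursor_mz)
    e$scan_id <- s$scan_id
    e
  }))
  est <- est[order(est$scan_id), , drop = FALSE]  # scan-order invariance
  rownames(est) <- NULL
  max_ma <- max(est$ma_median)
  rep <- list(sample_name = sample_name, ion_estimates = est,
              max_ma = max_ma, threshold = threshold,
              verdict = if (max_ma > threshold) "above_threshold"
                        else "below_threshold",
              empty = FALSE)
  class(rep) <- "sample_report"
  rep
}

#' @export
print.sample_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("<sample_report> %s: no usable MS2 scans\n", x$sample_name))
    return(invisible(x))
  }
  cat(sprintf("<sample_report> %s: %d ions, max estimated MA %.1f (threshold %g)\n",
              x$sample_name, nrow(x$ion_estimates), x$max_ma, x$threshold))
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (x$verdict == "above_threshold")
                " - sample contains high-MA molecules" else ""))
  invisible(x)
}

#' Serialize a sample report
#'
#' Writes the verdict and per-ion estimates as JSON, and optionally the
#' ion table as CSV.
#'
#' @param report a `sample_report`.
#' @param json_path output JSON path.
#' @param csv_path optional output CSV path for the ion table.
#' @return `json_path`, invisibly.
#' @export
write_sample_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "sample_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$ion_estimates, csv_path, row.names = FALSE)
  invisible(json_path)
}
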