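#' Data-dependent acquisition: top-N precursor selection with dynamic
#' exclusion
#'
#' Emulates the acquisition logic used for mixture runs: per MS1 survey
#' scan, the `top_n` most intense ions inside the m/z window that are not
#' currently excluded are scheduled for MS2. An ion selected twice within
#' `repeat_window` seconds becomes excluded for the next `exclusion`
#' seconds (so an ion picked at t = 0 s and t = 5 s is unavailable until
#' t = 35 s with the defaults). Ions are identified across scans by m/z
#' within `match_tol`.
#'
#' @param ms1 list of MS1 `ms_spectrum`, time-ordered (checked).
#' @param window_low,window_high precursor m/z window (default 300-500,
#'   the range where molecular masses take diverse MA values).
#' @param top_n precursors fragmented per survey scan (default 15).
#' @param repeat_window seconds within which a second selection triggers
#'   exclusion (default 10).
#' @param exclusion exclusion duration in seconds (default 30).
#' @param match_tol m/z tolerance for recognizing the same ion (default
#'   0.01 Th).
#' @return data.frame schedule: `scan_index`, `time`, `mz`, `intensity`,
#'   `ion_id`.
#' @export
dda_select <- function(ms1, window_low = 300, window_high = 500,
                       top_n = 15, repeat_window = 10, exclusion = 30,
                       match_tol = 0.01) {
  stopifnot(length(ms1) > 0L)
  lv <- vapply(ms1, function(s) s$ms_level, 0L)
  stopifnot(all(lv == 1L))
  times <- vapply(ms1, function(s) s$retention_time, 0)
  if (is.unsorted(times)) stop("MS1 spectra must be time-ordered")

  ion_mz <- numeric(0)          # representative m/z per known ion
  last_sel <- numeric(0)        # most recent selection time
  excluded_until <- numeric(0)  # exclusion expiry
  sched <- list()
  for (i in seq_along(ms1)) {
    t <- times[i]
    pk <- ms1[[i]]$peaks
    pk <- pk[pk$mz >= window_low & pk$mz <= window_high, , drop = FALSE]
    if (nrow(pk) == 0L) next
    pk <- pk[order(-pk$intensity, pk$mz), , drop = FALSE]
    picked <- 0L
    for (j in seq_len(nrow(pk))) {
      if (picked >= top_n) break
      id <- if (length(ion_mz))
        which(abs(ion_mz - pk$mz[j]) <= match_tol)[1] else NA_integer_
      if (is.na(id)) {
        ion_mz <- c(ion_mz, pk$mz[j])
        last_sel <- c(last_sel, -Inf)
        excluded_until <- c(excluded_until, -Inf)
        id <- length(ion_mz)
      }
      if (t < excluded_until[id]) next
      # select
      picked <- picked + 1L
      sched[[length(sched) + 1L]] <-
        data.frame(scan_index = i, time = t, mz = pk$mz[j],
                   intensity = pk$intensity[j], ion_id = id)
      if (t - last_sel[id] <= repeat_window)
        excluded_until[id] <- t + exclusion
      last_sel[id] <- t
    }
  }
  if (length(sched) == 0L)
    return(data.frame(scan_index = integer(), time = numeric(),
                      mz = numeric(), intensity = numeric(),
                      ion_id = integer()))
  out <- do.call(rbind, sched)
  rownames(out) <- NULL
  out
}
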