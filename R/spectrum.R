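#' Centroided mass spectrum
#'
#' A single MS1 survey scan or MS2 fragmentation scan: a peak list (m/z,
#' intensity) plus scan metadata. MS2 spectra must carry the precursor m/z
#' of the isolated ion.
#'
#' @param mz numeric vector of mass-to-charge values (Thomson), positive.
#' @param intensity numeric vector of intensities, non-negative.
#' @param ms_level 1 (survey) or 2 (fragmentation).
#' @param precursor_mz precursor m/z, required when `ms_level = 2`.
#' @param retention_time scan time in seconds.
#' @param scan_id scan identifier.
#' @return an `ms_spectrum`; peaks are stored sorted by m/z.
#' @export
spectrum <- function(mz, intensity, ms_level = 2L, precursor_mz = NULL,
                     retention_time = NA_real_, scan_id = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0L) {
    stopifnot(all(mz > 0), all(intensity >= 0))
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]
  }
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level %in% c(1L, 2L))
  if (ms_level == 2L && (is.null(precursor_mz) || is.na(precursor_mz)))
    stop("an MS2 spectrum requires precursor_mz")
  structure(list(peaks = data.frame(mz = as.numeric(mz),
                                    intensity = as.numeric(intensity)),
                 ms_level = ms_level,
                 precursor_mz = if (is.null(precursor_mz)) NA_real_ else as.numeric(precursor_mz),
                 retention_time = as.numeric(retention_time),
                 scan_id = as.character(scan_id)),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> MS%d scan %s: %d peaks%s%s\n", x$ms_level,
              x$scan_id, nrow(x$peaks),
              if (!is.na(x$precursor_mz))
                sprintf(", precursor m/z %.4f", x$precursor_mz) else "",
              if (!is.na(x$retention_time))
                sprintf(", RT %.1f s", x$retention_time) else ""))
  invisible(x)
}

#' Read spectra from an MGF or mzML file
#'
#' Dispatches on the file extension. MGF parsing is done in-package (the
#' format is line-oriented text); mzML goes through mzR. MS2 records
#' lacking a precursor are skipped with a message; profile-mode mzML
#' spectra are rejected with guidance to centroid first.
#'
#' @param path path to a `.mgf` or `.mzML` file.
#' @return list of `ms_spectrum` (possibly empty, with a warning).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("cannot read spectra: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
                mgf = read_mgf(path),
                mzml = read_mzml(path),
                stop("unsupported spectra format: .", ext,
                     " (use .mgf or .mzML)"))
  if (length(out) == 0L) warning("no spectra read from ", path)
  out
}

#' Read a Mascot Generic Format (MGF) file
#'
#' Understands `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`,
#' `RTINSECONDS` and an optional non-standard `MSLEVEL` header (used by
#' [write_mgf()] so that synthetic runs can carry MS1 survey scans; a block
#' without `MSLEVEL` is MS2 if it has a `PEPMASS`). MS2 blocks without a
#' precursor are skipped with a message.
#'
#' @param path path to the MGF file.
#' @return list of `ms_spectrum`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE) & grepl("^[A-Z]", block)
    fields <- block[hdr]
    keyval <- strsplit(fields, "=", fixed = TRUE)
    keys <- vapply(keyval, `[[`, "", 1L)
    vals <- vapply(keyval, function(x) paste(x[-1L], collapse = "="), "")
    getf <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    peak_lines <- block[!hdr & nzchar(trimws(block))]
    pk <- if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                                   function(x) as.numeric(x[1:2])))
      mat[stats::complete.cases(mat), , drop = FALSE]
    } else matrix(numeric(), ncol = 2)
    pepmass <- suppressWarnings(as.numeric(strsplit(getf("PEPMASS"), " ")[[1]][1]))
    lvl <- getf("MSLEVEL")
    ms_level <- if (!is.na(lvl)) as.integer(lvl) else 2L
    rt <- suppressWarnings(as.numeric(getf("RTINSECONDS")))
    ttl <- getf("TITLE")
    if (ms_level == 2L && (length(pepmass) == 0L || is.na(pepmass))) {
      message(sprintf("skipping MGF block %d (%s): MS2 scan without precursor",
                      b, if (is.na(ttl)) "untitled" else ttl))
      next
    }
    out[[length(out) + 1L]] <- spectrum(
      mz = pk[, 1], intensity = pk[, 2], ms_level = ms_level,
      precursor_mz = if (ms_level == 2L) pepmass else NULL,
      retention_time = rt,
      scan_id = if (is.na(ttl)) sprintf("scan=%d", b) else ttl)
  }
  out
}

#' Write spectra as an MGF file
#'
#' MS1 scans are written with a non-standard `MSLEVEL=1` header (and no
#' `PEPMASS`), so a mixed MS1+MS2 synthetic run round-trips through
#' [read_mgf()]. Output is deterministic for identical input.
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "ms_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$scan_id), con)
    writeLines(sprintf("MSLEVEL=%d", s$ms_level), con)
    if (s$ms_level == 2L)
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$retention_time))
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read an mzML file via mzR
#'
#' @param path path to a centroided mzML file.
#' @return list of `ms_spectrum`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) return(list())
  if ("centroided" %in% names(hd) && any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra found in ", path,
         "; centroid the data before peak counting")
  out <- list()
  for (i in seq_len(nrow(hd))) {
    pk <- mzR::peaks(fh, i)
    lvl <- hd$msLevel[i]
    prec <- hd$precursorMZ[i]
    if (lvl >= 2L && (is.na(prec) || prec <= 0)) {
      message(sprintf("skipping mzML scan %d: MS2 scan without precursor", i))
      next
    }
    out[[length(out) + 1L]] <- spectrum(
      mz = pk[, 1], intensity = pk[, 2],
      ms_level = min(lvl, 2L),
      precursor_mz = if (lvl >= 2L) prec else NULL,
      retention_time = hd$retentionTime[i],
      scan_id = sprintf("scan=%d", hd$acquisitionNum[i]))
  }
  out
}

#' Write spectra as an mzML file via mzR
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  n <- length(spectra)
  stopifnot(n > 0L)
  pks <- lapply(spectra, function(s) as.matrix(s$peaks))
  rt <- vapply(spectra, function(s)
    if (is.na(s$retention_time)) 0 else s$retention_time, 0)
  lvl <- vapply(spectra, function(s) s$ms_level, 0L)
  npk <- vapply(pks, nrow, 0L)
  base_i <- vapply(pks, function(p) if (nrow(p)) max(p[, 2]) else 0, 0)
  base_mz <- vapply(pks, function(p)
    if (nrow(p)) p[which.max(p[, 2]), 1] else 0, 0)
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = rep(1L, n), peaksCount = npk, totIonCurrent =
      vapply(pks, function(p) sum(p[, 2]), 0),
    retentionTime = rt, basePeakMZ = base_mz, basePeakIntensity = base_i,
    collisionEnergy = ifelse(lvl == 2L, 45, 0),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0, 0),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0, 0),
    precursorScanNum = rep(0L, n),
    precursorMZ = vapply(spectra, function(s)
      if (is.na(s$precursor_mz)) 0 else s$precursor_mz, 0),
    precursorCharge = ifelse(lvl == 2L, 1L, 0L),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = vapply(spectra, function(s)
      if (is.na(s$precursor_mz)) NA_real_ else s$precursor_mz, 0),
    isolationWindowLowerOffset = ifelse(lvl == 2L, 0.25, NA_real_),
    isolationWindowUpperOffset = ifelse(lvl == 2L, 0.25, NA_real_),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n))
  mzR::writeMSData(pks, file = path, header = hd, outformat = "mzml")
  invisible(path)
}
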