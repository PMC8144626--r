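test_that("spectrum objects sort peaks and enforce precursor metadata", {
  s <- spectrum(c(300, 100, 200), c(1, 2, 3), ms_level = 1L)
  expect_equal(s$peaks$mz, c(100, 200, 300))
  expect_equal(s$peaks$intensity, c(2, 3, 1))
  expect_error(spectrum(100, 1, ms_level = 2L), "precursor")
})

test_that("MGF files round-trip mixed MS1/MS2 runs deterministically", {
  dir <- withr::local_tempdir()
  s1 <- spectrum(c(310.2, 420.5), c(100, 50), ms_level = 1L,
                 retention_time = 0, scan_id = "ms1_1")
  s2 <- make_spectrum(5, spectrum_law(), precursor_mz = 350.123,
                      retention_time = 1.5, scan_id = "ms2_1", seed = 13)
  p1 <- file.path(dir, "run.mgf")
  write_mgf(list(s1, s2), p1)
  rd <- read_spectra(p1)
  expect_length(rd, 2L)
  expect_equal(vapply(rd, function(s) s$ms_level, 0L), c(1L, 2L))
  expect_equal(rd[[2]]$precursor_mz, 350.123)
  expect_equal(nrow(rd[[2]]$peaks), nrow(s2$peaks))
  expect_equal(rd[[2]]$peaks$mz, s2$peaks$mz, tolerance = 1e-6)
  p2 <- file.path(dir, "run2.mgf")
  write_mgf(rd, p2)
  write_mgf(read_spectra(p2), file.path(dir, "run3.mgf"))
  expect_identical(readLines(file.path(dir, "run3.mgf")), readLines(p2))
})

test_that("MS2 blocks without precursor are skipped with a message", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.mgf")
  writeLines(c("BEGIN IONS", "TITLE=nopep", "100.1 5", "END IONS", "",
               "BEGIN IONS", "TITLE=good", "PEPMASS=400.2", "100.1 5",
               "END IONS"), p)
  expect_message(rd <- read_mgf(p), "without precursor")
  expect_length(rd, 1L)
  expect_equal(rd[[1]]$scan_id, "good")
})

test_that("empty or missing spectra files are handled gracefully", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.mgf")
  writeLines(character(0), p)
  expect_warning(rd <- read_spectra(p), "no spectra")
  expect_length(rd, 0L)
  expect_error(read_spectra(file.path(dir, "nothere.mgf")), "no such file")
  writeLines("x", file.path(dir, "x.txt"))
  expect_error(read_spectra(file.path(dir, "x.txt")), "unsupported")
})

test_that("mzML round-trips through mzR", {
  dir <- withr::local_tempdir()
  s1 <- spectrum(c(310.2, 420.5), c(100, 50), ms_level = 1L,
                 retention_time = 0, scan_id = "s1")
  s2 <- make_spectrum(7, spectrum_law(), precursor_mz = 401.3,
                      retention_time = 2, scan_id = "s2", seed = 3)
  p <- file.path(dir, "run.mzML")
  write_mzml(list(s1, s2), p)
  rd <- read_spectra(p)
  expect_length(rd, 2L)
  expect_equal(vapply(rd, function(s) s$ms_level, 0L), c(1L, 2L))
  expect_equal(rd[[2]]$precursor_mz, 401.3, tolerance = 1e-6)
  expect_equal(nrow(rd[[2]]$peaks), nrow(s2$peaks))
})

test_that("noise filtering implements the threshold arithmetic", {
  s <- spectrum(mz = seq(100, 114), intensity = c(rep(100, 10), rep(0.01, 5)),
                ms_level = 2L, precursor_mz = 400)
  f <- noise_filter(relative_threshold = 0.01)
  pc <- filter_peaks(s, f)
  expect_equal(pc$raw_peaks, 15L)
  expect_equal(pc$filtered_peaks, 10L)
  expect_identical(pc$filter_params, f)

  ident <- filter_peaks(s, noise_filter(0, 0))
  expect_equal(ident$filtered_peaks, ident$raw_peaks)

  windowed <- filter_peaks(s, noise_filter(0, 0, min_mz = 105))
  expect_equal(windowed$filtered_peaks, sum(s$peaks$mz >= 105))

  empty <- spectrum(numeric(0), numeric(0), ms_level = 1L)
  expect_equal(filter_peaks(empty, f)$filtered_peaks, 0L)
})

test_that("filtering is idempotent", {
  set.seed(77)
  for (i in 1:20) {
    s <- make_spectrum(sample(5:25, 1),
                       spectrum_law(noise_sd = 5, n_noise_peaks = 30))
    f <- noise_filter(relative_threshold = runif(1, 0.001, 0.1))
    once <- filter_peaks(s, f)
    twice <- filter_peaks(once$spectrum, f)
    expect_equal(twice$filtered_peaks, once$filtered_peaks)
    expect_equal(twice$spectrum$peaks, once$spectrum$peaks)
  }
})

test_that("standard counts average over matching precursors only", {
  law <- spectrum_law()
  mk <- function(n_pk, prec) {
    spectrum(mz = seq_len(n_pk) + 100, intensity = rep(100, n_pk),
             ms_level = 2L, precursor_mz = prec)
  }
  sp <- list(mk(10, 400.00), mk(12, 400.01), mk(14, 399.99),
             mk(50, 450.00))
  expect_equal(count_for_standard(sp, 400, tolerance = 0.25), 12)
  expect_equal(count_for_standard(sp, 450, tolerance = 0.25), 50)
  expect_error(count_for_standard(sp, 500, tolerance = 0.25), "500")
})
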