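test_that("doubling chains carry their exact assembly index", {
  for (k in 0:3) {
    g <- make_doubling_chain(k)
    expect_equal(n_bonds(g), 2^k)
    expect_equal(attr(g, "true_ma"), k + 1L)
    expect_equal(split_branch_ma(g)$ma, k + 1L)
    expect_equal(exact_ma(g), k + 1L)
  }
  expect_error(make_doubling_chain(10), "molfile")
})

test_that("random molecules are reproducible, connected and valence-legal", {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
               Br = 1, I = 1, Si = 4, B = 3)
  units <- c(single = 1, double = 2, triple = 3)
  for (s in 1:30) {
    n <- (s %% 8) + 1L
    g <- make_random_molecule(n, seed = s)
    expect_equal(n_bonds(g), n)
    g2 <- make_random_molecule(n, seed = s)
    expect_identical(g$bonds, g2$bonds)
    expect_identical(canonical_code(g), canonical_code(g2))
    # per-atom bond-order units never exceed the element's valence
    load <- tapply(rep(units[g$bonds$order], 2L),
                   c(g$bonds$a1, g$bonds$a2), sum)
    expect_true(all(load <= valence[g$atoms$element[as.integer(names(load))]]))
    # writable and re-readable as chemistry
    rt <- read_molfile(write_molfile(g))
    expect_identical(canonical_code(rt), canonical_code(g))
  }
  expect_equal(n_bonds(make_random_molecule(1, seed = 1)), 1L)
})

test_that("synthetic spectra obey the generating peak-count law", {
  law0 <- spectrum_law(slope = 10, intercept = 0, noise_sd = 0,
                       n_noise_peaks = 0)
  s <- make_spectrum(3, law0, seed = 1)
  expect_equal(nrow(s$peaks), 30L)
  expect_equal(attr(s, "true_peaks"), 30L)

  # decoys always fall below the default filter
  lawn <- spectrum_law(slope = 10, noise_sd = 4, n_noise_peaks = 25)
  for (seed in 1:10) {
    s <- make_spectrum(8, lawn, seed = seed)
    expect_equal(filter_peaks(s)$filtered_peaks, attr(s, "true_peaks"))
    expect_equal(nrow(s$peaks), attr(s, "true_peaks") + 25L)
  }
})

test_that("seeded generation produces byte-identical MGF output", {
  dir <- withr::local_tempdir()
  prof <- bio_profile()
  p1 <- file.path(dir, "a.mgf"); p2 <- file.path(dir, "b.mgf")
  make_run(prof, spectrum_law(noise_sd = 5, n_noise_peaks = 10),
           path = p1, seed = 99)
  make_run(prof, spectrum_law(noise_sd = 5, n_noise_peaks = 10),
           path = p2, seed = 99)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("mixture runs fragment the top 15 ions per survey cycle", {
  run <- make_run(bio_profile(20), spectrum_law(), n_cycles = 1, seed = 4)
  expect_equal(sum(run$schedule$scan_index == 1), 15L)
  lv <- vapply(run$spectra, function(s) s$ms_level, 0L)
  expect_equal(sum(lv == 1L), 1L)
  expect_equal(sum(lv == 2L), 15L)
  # generated runs parse back through the spectra reader
  dir <- withr::local_tempdir()
  p <- file.path(dir, "run.mgf")
  make_run(bio_profile(20), spectrum_law(), path = p, n_cycles = 2, seed = 4)
  rd <- read_spectra(p)
  expect_gt(length(rd), 2L)
  expect_true(all(vapply(rd, function(s) s$ms_level, 0L) %in% 1:2))
})

test_that("the fixture corpus regenerates exactly from its manifest", {
  fx1 <- fixture_manifest(n_random = 10, max_bonds = 6, chains = 0:2,
                          seed = 17)
  fx2 <- fixture_manifest(n_random = 10, max_bonds = 6, chains = 0:2,
                          seed = 17)
  expect_identical(fx1$manifest, fx2$manifest)
  expect_identical(vapply(fx1$graphs, canonical_code, ""),
                   vapply(fx2$graphs, canonical_code, ""))
  # manifest entries regenerate the same molecule individually
  r <- fx1$manifest[fx1$manifest$kind == "random", ][1, ]
  g <- make_random_molecule(r$n_bonds, seed = r$seed)
  expect_equal(split_branch_ma(g)$ma, r$ma)
})

test_that("the calibration loop closes over generated standards", {
  # generator law -> spectra -> counting -> regression recovers the slope
  law <- spectrum_law(slope = 12, intercept = 5, noise_sd = 6,
                      n_noise_peaks = 15)
  set.seed(55)
  ma <- runif(300, 5, 25)
  counts <- vapply(ma, function(m)
    filter_peaks(make_spectrum(m, law))$filtered_peaks, 0L)
  m <- fit_calibration(data.frame(peak_count = counts, ma = ma))
  expect_lt(abs(1 / m$lines$slope[2] - 12) / 12, 0.05)
})
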