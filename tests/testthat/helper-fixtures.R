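# Shared builders for test inputs; everything is constructed in code.

# Linear chain of k identical bonds between carbons (or given elements).
chain_graph <- function(k, element = "C", order = "single") {
  mol_graph(data.frame(element = rep(element, k + 1L)),
            data.frame(a1 = seq_len(k), a2 = seq_len(k) + 1L, order = order),
            name = sprintf("chain_%d", k))
}

# Hand-written V2000 molfile for CO2 (no explicit hydrogens).
co2_molfile <- function() {
  paste(c("carbon dioxide", "  test", "",
          "  3  2  0  0  0  0  0  0  0  0999 V2000",
          "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
          "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
          "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
          "  1  2  2  0", "  2  3  2  0", "M  END"), collapse = "\n")
}

# Methane with four explicit hydrogens.
methane_molfile <- function() {
  at <- function(el) sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", el)
  paste(c("methane", "  test", "",
          "  5  4  0  0  0  0  0  0  0  0999 V2000",
          at("C"), at("H"), at("H"), at("H"), at("H"),
          "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
          "M  END"), collapse = "\n")
}

# Benzene written with aromatic (order 4) bonds, to exercise kekulization.
benzene_aromatic_molfile <- function() {
  at <- "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0"
  bd <- sprintf("%3d%3d  4  0", 1:6, c(2:6, 1))
  paste(c("benzene", "  test", "",
          "  6  6  0  0  0  0  0  0  0  0999 V2000",
          rep(at, 6), bd, "M  END"), collapse = "\n")
}

# A calibration model with known lines, bypassing fitting.
toy_calibration <- function(slope = 0.1,
                            intercepts = c(-1, 0, 1)) {
  structure(list(lines = data.frame(tau = c(0.05, 0.5, 0.95),
                                    slope = slope, intercept = intercepts),
                 n_points = 3L, pearson_r = 1, peak_range = c(0, 300)),
            class = "ma_calibration")
}

# Mixture profiles for end-to-end runs: one high-MA ion vs all-low.
bio_profile <- function(n = 20) {
  data.frame(mz = seq(305, 495, length.out = n),
             ma = c(rep(8, n - 1), 20),
             intensity = seq(1e5, 2e5, length.out = n))
}
abio_profile <- function(n = 20) {
  data.frame(mz = seq(305, 495, length.out = n),
             ma = rep(c(4, 7, 10), length.out = n),
             intensity = seq(1e5, 2e5, length.out = n))
}

# Calibration standards generated through the spectrum pipeline.
standards_table <- function(n = 500, law = spectrum_law(slope = 10,
                                                        noise_sd = 10,
                                                        n_noise_peaks = 20),
                            seed = 1) {
  set.seed(seed)
  ma <- stats::runif(n, 5, 25)
  counts <- vapply(ma, function(m)
    filter_peaks(make_spectrum(m, law))$filtered_peaks, 0L)
  data.frame(peak_count = counts, ma = ma)
}
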