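# Deterministic generators of test inputs: molecular graphs with known
# assembly indices, MS2 spectra that obey a prescribed peaks-vs-MA law,
# and full MS1+MS2 mixture runs. Everything is reproducible from a seed.

# Run `code` under a temporary RNG state seeded with `seed` (NULL = use
# the current stream).
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code())
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code()
}

#' Carbon chain of 2^k identical bonds (known assembly index)
#'
#' A linear chain of `2^k` identical C-C single bonds can be built by
#' repeated doubling, so its assembly index is exactly `k + 1` (eq1
#' convention). These are the exact anchors of the oracle suite.
#'
#' @param k non-negative integer, at most 9 (V2000 atom-count limit).
#' @return a `mol_graph` with attribute `true_ma` = `k + 1`.
#' @export
make_doubling_chain <- function(k) {
  stopifnot(length(k) == 1L, k >= 0, k == floor(k))
  if (k > 9) stop("k > 9 exceeds the V2000 molfile atom limit (2^k + 1 atoms)")
  m <- 2^k
  g <- mol_graph(data.frame(element = rep("C", m + 1L)),
                 data.frame(a1 = seq_len(m), a2 = seq_len(m) + 1L,
                            order = "single"),
                 name = sprintf("doubling_chain_k%d", k),
                 source_format = "generated")
  attr(g, "true_ma") <- as.integer(k + 1)
  g
}

#' Random connected, valence-legal molecular graph
#'
#' Grows a molecule bond by bond: each step either attaches a new atom to
#' an atom with free valence or (with small probability) closes a ring.
#' With probability `duplication_bias` the new bond copies the element and
#' order of an existing bond, which spreads the achieved assembly index
#' across the corpus. Intended for the oracle comparison suite, so keep
#' `n_bonds` at or below the [exact_ma()] limit there.
#'
#' @param n_bonds number of bonds (>= 1).
#' @param elements element pool to draw from (repetition weights allowed).
#' @param duplication_bias probability that a new bond copies an existing
#'   bond's label.
#' @param ring_prob probability of attempting a ring closure per step.
#' @param seed optional seed for reproducibility.
#' @return a `mol_graph`.
#' @export
make_random_molecule <- function(n_bonds, elements = c("C", "C", "C", "N", "O"),
                                 duplication_bias = 0.5, ring_prob = 0.1,
                                 seed = NULL) {
  stopifnot(n_bonds >= 1)
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L, Cl = 1L,
               Br = 1L, I = 1L, Si = 4L, B = 3L)
  if (!all(elements %in% names(valence)))
    stop("unsupported element(s): ",
         paste(setdiff(elements, names(valence)), collapse = ", "))
  .with_seed(seed, function() {
    ord_units <- c(single = 1L, double = 2L, triple = 3L)
    # orders usable for a new atom on `at`, keeping at least one free
    # valence in the molecule while more bonds are still needed
    attach_orders <- function(fa, ve, total_free, more_needed) {
      u <- ord_units[ord_units <= min(fa, ve)]
      if (more_needed) u <- u[(total_free - u) + (ve - u) >= 1L]
      names(u)
    }
    draw_from <- function(opts) {
      if (length(opts) == 0L) return(NULL)
      if (length(opts) > 1L && stats::runif(1) < 0.2)
        sample(opts[-1L], 1L) else opts[1L]
    }
    # first bond
    repeat {
      el <- sample(elements, 2L, replace = TRUE)
      opts <- attach_orders(valence[el[1]], valence[el[2]],
                            valence[el[1]], n_bonds > 1L)
      ord <- draw_from(opts)
      if (!is.null(ord)) break
    }
    atoms <- el
    bonds <- data.frame(a1 = 1L, a2 = 2L, order = ord)
    used <- c(ord_units[ord], ord_units[ord])
    for (b in seq_len(n_bonds - 1L) + 1L) {
      free_v <- valence[atoms] - used
      free <- which(free_v >= 1L)
      total_free <- sum(free_v)
      if (length(free) == 0L)
        stop("unsatisfiable valence request: no free valence left")
      more <- b < n_bonds
      placed <- FALSE
      if (stats::runif(1) < ring_prob && length(free) >= 2L) {
        cand <- utils::combn(free, 2L)
        keyed <- paste(pmin(cand[1, ], cand[2, ]), pmax(cand[1, ], cand[2, ]))
        existing <- paste(bonds$a1, bonds$a2)
        ok <- which(!(keyed %in% existing))
        if (length(ok)) {
          pick <- cand[, ok[sample(length(ok), 1L)]]
          cap <- min(free_v[pick])
          u <- ord_units[ord_units <= cap]
          # ring closure consumes valence at both ends
          if (more) u <- u[total_free - 2L * u >= 1L]
          ord <- draw_from(names(u))
          if (!is.null(ord)) {
            bonds <- rbind(bonds, data.frame(a1 = pick[1], a2 = pick[2],
                                             order = ord))
            used[pick] <- used[pick] + ord_units[ord]
            placed <- TRUE
          }
        }
      }
      if (!placed) {
        at_order <- if (length(free) == 1L) free else sample(free)
        for (at in at_order) {
          if (stats::runif(1) < duplication_bias) {
            src <- bonds[sample(nrow(bonds), 1L), ]
            new_el <- sample(c(atoms[src$a1], atoms[src$a2]), 1L)
            opts <- attach_orders(free_v[at], valence[new_el], total_free, more)
            ord <- if (src$order %in% opts) src$order else draw_from(opts)
          } else {
            new_el <- sample(elements, 1L)
            opts <- attach_orders(free_v[at], valence[new_el], total_free, more)
            ord <- draw_from(opts)
          }
          if (is.null(ord)) next
          atoms <- c(atoms, new_el)
          bonds <- rbind(bonds, data.frame(a1 = at, a2 = length(atoms),
                                           order = ord))
          used[at] <- used[at] + ord_units[ord]
          used <- c(used, ord_units[ord])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("unsatisfiable valence request: cannot place bond ", b)
    }
    mol_graph(data.frame(element = atoms), bonds,
              name = sprintf("random_molecule_%db", n_bonds),
              source_format = "generated")
  })
}

#' Linear law linking MS2 peak count to assembly index
#'
#' The generative model behind synthetic spectra: an ion of assembly index
#' `ma` produces `round(slope * ma + intercept + N(0, noise_sd))`
#' above-threshold fragment peaks (clamped at 1), plus `n_noise_peaks`
#' sub-threshold decoys. Defaults map MA 5-25 onto 50-250 peaks, a
#' plausible instrument range; they are configuration, not a claim about
#' any instrument.
#'
#' @param slope,intercept linear coefficients (slope > 0).
#' @param noise_sd standard deviation of peak-count noise.
#' @param n_noise_peaks decoy peaks per spectrum, placed at 0.1x the
#'   default filter threshold so they are always filtered out.
#' @return a `spectrum_law` list.
#' @export
spectrum_law <- function(slope = 10, intercept = 0, noise_sd = 0,
                         n_noise_peaks = 0) {
  stopifnot(slope > 0, noise_sd >= 0, n_noise_peaks >= 0)
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 n_noise_peaks = as.integer(n_noise_peaks)),
            class = "spectrum_law")
}

#' Synthetic MS2 spectrum for an ion of known assembly index
#'
#' @param ma assembly index of the (virtual) precursor ion, >= 1.
#' @param law a [spectrum_law()].
#' @param precursor_mz precursor m/z; drawn uniformly in 300-500 if NULL.
#' @param base_intensity base-peak intensity (arbitrary units).
#' @param retention_time,scan_id scan metadata.
#' @param seed optional seed.
#' @return an `ms_spectrum` with attribute `true_peaks`: the number of
#'   above-threshold peaks generated.
#' @export
make_spectrum <- function(ma, law = spectrum_law(), precursor_mz = NULL,
                          base_intensity = 1000, retention_time = NA_real_,
                          scan_id = NA_character_, seed = NULL) {
  stopifnot(ma >= 1, inherits(law, "spectrum_law"))
  .with_seed(seed, function() {
    if (is.null(precursor_mz)) precursor_mz <- stats::runif(1, 300, 500)
    n <- max(1L, as.integer(round(law$slope * ma + law$intercept +
                                    stats::rnorm(1, 0, law$noise_sd))))
    # real peaks: intensities in [2%, 100%] of base, all above the 1%
    # default relative threshold
    mz <- sort(stats::runif(n, 50, precursor_mz))
    while (anyDuplicated(mz)) mz <- sort(stats::runif(n, 50, precursor_mz))
    intensity <- base_intensity * stats::runif(n, 0.02, 1)
    intensity[which.max(intensity)] <- base_intensity
    if (law$n_noise_peaks > 0L) {
      nz <- law$n_noise_peaks
      mz <- c(mz, stats::runif(nz, 50, precursor_mz))
      intensity <- c(intensity, rep(0.1 * 0.01 * base_intensity, nz))
    }
    s <- spectrum(mz, intensity, ms_level = 2L, precursor_mz = precursor_mz,
                  retention_time = retention_time, scan_id = scan_id)
    attr(s, "true_peaks") <- n
    s
  })
}

#' Synthetic mixture run: MS1 survey scans plus DDA-selected MS2 scans
#'
#' Produces the time-ordered spectra of a direct-infusion run over a
#' mixture whose ions have the given m/z, assembly index and MS1
#' intensity. Precursor selection is delegated to [dda_select()] (same
#' top-N and dynamic-exclusion logic as the analysis), and each selected
#' ion receives an MS2 spectrum drawn from `law`.
#'
#' @param profile data.frame with columns `mz`, `ma`, `intensity`; one row
#'   per mixture ion.
#' @param law a [spectrum_law()].
#' @param path optional output path (`.mgf` or `.mzML`).
#' @param n_cycles number of MS1 survey cycles (default 4).
#' @param cycle_time seconds between MS1 scans (default 3).
#' @param top_n,window DDA parameters (defaults 15 and 300-500).
#' @param seed optional seed; the run is byte-identical for a fixed seed.
#' @return invisibly, a list with `spectra` (time-ordered list of
#'   `ms_spectrum`), `schedule` (the [dda_select()] table) and `path`.
#' @export
make_run <- function(profile, law = spectrum_law(), path = NULL,
                     n_cycles = 4, cycle_time = 3, top_n = 15,
                     window = c(300, 500), seed = NULL) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 1L,
            all(c("mz", "ma", "intensity") %in% names(profile)))
  .with_seed(seed, function() {
    ms1 <- lapply(seq_len(n_cycles), function(cy)
      spectrum(profile$mz, profile$intensity, ms_level = 1L,
               retention_time = (cy - 1L) * cycle_time,
               scan_id = sprintf("ms1_cycle%02d", cy)))
    sched <- dda_select(ms1, window_low = window[1], window_high = window[2],
                        top_n = top_n)
    spectra <- list()
    for (cy in seq_len(n_cycles)) {
      spectra[[length(spectra) + 1L]] <- ms1[[cy]]
      sel <- sched[sched$scan_index == cy, , drop = FALSE]
      if (nrow(sel) == 0L) next
      dt <- cycle_time / (nrow(sel) + 1L)
      for (r in seq_len(nrow(sel))) {
        ion <- which.min(abs(profile$mz - sel$mz[r]))
        spectra[[length(spectra) + 1L]] <- make_spectrum(
          ma = profile$ma[ion], law = law, precursor_mz = profile$mz[ion],
          retention_time = sel$time[r] + r * dt,
          scan_id = sprintf("ms2_cycle%02d_%02d_mz%.2f", cy, r,
                            profile$mz[ion]))
      }
    }
    if (!is.null(path)) {
      if (tolower(tools::file_ext(path)) == "mgf") write_mgf(spectra, path)
      else write_mzml(spectra, path)
    }
    invisible(list(spectra = spectra, schedule = sched, path = path))
  })
}

#' Reproducible fixture corpus with manifest
#'
#' Generates doubling chains (known MA) and random valence-legal molecules
#' (split-branch MA recorded) together with a manifest from which the set
#' can be regenerated exactly.
#'
#' @param n_random number of random molecules.
#' @param max_bonds bond-count cap for the random molecules (uniform in
#'   1..max_bonds).
#' @param chains doubling-chain exponents to include.
#' @param seed corpus seed.
#' @return list with `graphs` (list of `mol_graph`) and `manifest`
#'   (data.frame: name, kind, n_bonds, seed, ma).
#' @export
fixture_manifest <- function(n_random = 50, max_bonds = 8, chains = 0:4,
                             seed = 1) {
  graphs <- list(); rows <- list()
  for (k in chains) {
    g <- make_doubling_chain(k)
    graphs[[length(graphs) + 1L]] <- g
    rows[[length(rows) + 1L]] <-
      data.frame(name = g$name, kind = "doubling_chain",
                 n_bonds = n_bonds(g), seed = NA_integer_,
                 ma = attr(g, "true_ma"))
  }
  sub_seeds <- .with_seed(seed, function()
    sample.int(1000000L, n_random + 1L))
  sizes <- .with_seed(sub_seeds[n_random + 1L], function()
    sample.int(max_bonds, n_random, replace = TRUE))
  for (i in seq_len(n_random)) {
    g <- make_random_molecule(sizes[i], seed = sub_seeds[i])
    g$name <- sprintf("random_%03d", i)
    graphs[[length(graphs) + 1L]] <- g
    rows[[length(rows) + 1L]] <-
      data.frame(name = g$name, kind = "random",
                 n_bonds = n_bonds(g), seed = sub_seeds[i],
                 ma = split_branch_ma(g)$ma)
  }
  list(graphs = graphs, manifest = do.call(rbind, rows))
}
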