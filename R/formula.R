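# Conventional (abridged IUPAC 2021) standard atomic weights for the
# elements that occur in small-molecule work. Values in Daltons.
.atomic_weights <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904,
  Kr = 83.798, Rb = 85.468, Sr = 87.62, Mo = 95.95, Ag = 107.868,
  Cd = 112.414, Sn = 118.710, Sb = 121.760, Te = 127.60, I = 126.904,
  Xe = 131.293, Cs = 132.905, Ba = 137.327, W = 183.84, Pt = 195.084,
  Au = 196.967, Hg = 200.592, Pb = 207.2, Bi = 208.980
)

#' Molecular formula of a graph
#'
#' Element counts including hydrogens carried over from the source record
#' (explicit or implicit); hydrogens are suppressed from the assembly graph
#' itself but retained here so that masses come out right.
#'
#' @param g a `mol_graph`.
#' @return named integer vector of element counts, class `mol_formula`.
#' @export
molecular_formula <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  if (!is.null(g$formula)) return(as_formula(g$formula))
  counts <- table(g$atoms$element)
  as_formula(stats::setNames(as.integer(counts), names(counts)))
}

as_formula <- function(x) {
  x <- x[x > 0]
  # Hill order: C, H, then alphabetical
  els <- names(x)
  key <- match(els, c("C", "H"))
  ord <- order(ifelse(is.na(key), 3L, key), els)
  structure(as.integer(x[ord]), names = els[ord], class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# "C47H51NO14" -> named counts
parse_formula_string <- function(s) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  els <- sub("[0-9]*$", "", parts)
  ns <- sub("^[A-Za-z]+", "", parts)
  counts <- ifelse(nzchar(ns), as.integer(ns), 1L)
  tab <- tapply(counts, els, sum)
  as_formula(stats::setNames(as.integer(tab), names(tab)))
}

#' Average molecular mass from a formula
#'
#' Sum of element count times conventional standard atomic weight;
#' displays customarily round to one decimal (e.g. 853.9 for paclitaxel,
#' C47H51NO14).
#'
#' @param f a `mol_formula`, a named count vector, or a formula string such
#'   as `"C47H51NO14"`.
#' @return mass in Daltons (numeric scalar, unrounded).
#' @export
average_mass <- function(f) {
  if (is.character(f) && length(f) == 1L) f <- parse_formula_string(f)
  if (length(f) == 0L) return(0)
  w <- .atomic_weights[names(f)]
  if (anyNA(w))
    stop("no tabulated atomic weight for element(s): ",
         paste(names(f)[is.na(w)], collapse = ", "))
  sum(unclass(f) * w)
}

#' Number of diastereomers from a stereocenter count
#'
#' `2^n` configurations for `n` stereocenters (e.g. 2048 for the 11 chiral
#' centers of paclitaxel). Stereocenters are taken as user input; the
#' package does not perceive them.
#'
#' @param n_stereocenters non-negative integer.
#' @return numeric count `2^n`.
#' @export
diastereomer_count <- function(n_stereocenters) {
  if (length(n_stereocenters) != 1L || is.na(n_stereocenters) ||
      n_stereocenters < 0 || n_stereocenters != floor(n_stereocenters))
    stop("n_stereocenters must be a single non-negative integer")
  2^n_stereocenters
}
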