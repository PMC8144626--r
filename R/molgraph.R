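#' Molecular graphs with bonds as assembly units
#'
#' A `mol_graph` is a hydrogen-suppressed, bond-labelled molecular graph:
#' the container on which assembly indices are computed. Atoms carry only an
#' element symbol; bonds carry an order category (`single`, `double`,
#' `triple`, or -- only when kekulization fails -- `aromatic`). Coordinates,
#' formal charges and stereochemistry are deliberately absent: the assembly
#' index is a function of labelled connectivity alone.
#'
#' @param atoms data.frame with column `element` (one row per heavy atom).
#' @param bonds data.frame with integer columns `a1`, `a2` and character
#'   column `order`; one row per bond between heavy atoms.
#' @param name free-text molecule name.
#' @param source_format provenance tag (`"molfile"`, `"sdf"`, `"smiles"`,
#'   `"generated"`, ...).
#' @param formula optional named integer vector of element counts including
#'   hydrogens, kept for formula/mass accounting only.
#'
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, name = "", source_format = "generated",
                      formula = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(is.character(atoms$element))
  n <- nrow(atoms)
  if (n == 0L) stop("a mol_graph needs at least one heavy atom")
  if (!all(atoms$element %in% names(.atomic_weights)))
    stop("unknown element symbol(s): ",
         paste(setdiff(atoms$element, names(.atomic_weights)), collapse = ", "))
  atoms <- data.frame(index = seq_len(n), element = atoms$element,
                      stringsAsFactors = FALSE)

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    if (any(bonds$a1 == bonds$a2)) stop("bond endpoints must be distinct atoms")
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n))
      stop("bond endpoint references a non-existent atom")
    if (!all(bonds$order %in% .bond_orders))
      stop("bond order must be one of: ", paste(.bond_orders, collapse = ", "))
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    key <- paste(bonds$a1, bonds$a2)
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  }

  g <- structure(list(atoms = atoms, bonds = bonds, name = name,
                      source_format = source_format, formula = formula),
                 class = "mol_graph")
  if (!mg_is_connected(g))
    stop("molecular graph is not connected (multi-component structures are rejected)")
  g
}

.bond_orders <- c("single", "double", "triple", "aromatic")

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds [%s]\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), x$source_format))
  invisible(x)
}

#' Number of bonds / heavy atoms in a molecular graph
#'
#' @param g a `mol_graph`.
#' @return integer count.
#' @export
n_bonds <- function(g) nrow(g$bonds)

#' @rdname n_bonds
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Bond labels of a molecular graph
#'
#' Two bonds are "identical" for assembly purposes iff their labels are
#' equal: the sorted pair of endpoint element symbols plus the bond order.
#'
#' @param g a `mol_graph`.
#' @return character vector, one label per bond, e.g. `"C-O:double"`.
#' @export
bond_labels <- function(g) {
  if (n_bonds(g) == 0L) return(character())
  e1 <- g$atoms$element[g$bonds$a1]
  e2 <- g$atoms$element[g$bonds$a2]
  lo <- ifelse(e1 <= e2, e1, e2)
  hi <- ifelse(e1 <= e2, e2, e1)
  paste0(lo, "-", hi, ":", g$bonds$order)
}

mg_is_connected <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(TRUE)
  if (n_bonds(g) == 0L) return(FALSE)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(g$bonds$a1, g$bonds$a2))
  igraph::is_connected(ig)
}

#' Extract the fragment induced by a set of bonds
#'
#' Returns the connected sub-structure made of the given bonds (atoms are
#' renumbered contiguously). Used to recurse on duplicated substructures.
#'
#' @param g a `mol_graph`.
#' @param bond_idx integer indices into `g$bonds`.
#' @return a `mol_graph` for the fragment.
#' @export
fragment_graph <- function(g, bond_idx) {
  b <- g$bonds[bond_idx, , drop = FALSE]
  at <- sort(unique(c(b$a1, b$a2)))
  map <- match(seq_len(n_atoms(g)), at)
  mol_graph(atoms = data.frame(element = g$atoms$element[at]),
            bonds = data.frame(a1 = map[b$a1], a2 = map[b$a2],
                               order = b$order),
            name = "", source_format = "fragment")
}

# Auxiliary coloured igraph used for canonical forms: one vertex per atom
# (coloured by element) and one per bond (coloured by order), bond-vertices
# linked to their two endpoints. Vertex colours must only be consistent
# within one graph; the label strings themselves go into the code.
mg_aux_graph <- function(g) {
  n <- n_atoms(g); m <- n_bonds(g)
  els <- g$atoms$element
  ords <- g$bonds$order
  el_lev <- sort(unique(els))
  or_lev <- sort(unique(ords))
  colors <- c(match(els, el_lev),
              length(el_lev) + match(ords, or_lev))
  if (m > 0L) {
    edges <- rbind(cbind(g$bonds$a1, n + seq_len(m)),
                   cbind(g$bonds$a2, n + seq_len(m)))
  } else {
    edges <- matrix(integer(), ncol = 2)
  }
  ig <- igraph::make_empty_graph(n + m, directed = FALSE)
  if (nrow(edges) > 0L) ig <- igraph::add_edges(ig, t(edges))
  list(graph = ig, colors = as.integer(colors),
       labels = c(els, ords), n = n, m = m)
}

#' Canonical code of a molecular graph
#'
#' An opaque string equal for two graphs iff they are isomorphic respecting
#' element symbols and bond orders. Built from a BLISS canonical labelling
#' of an auxiliary coloured graph, so it is invariant under any reindexing
#' of atoms or bonds.
#'
#' @param g a `mol_graph`.
#' @return character scalar.
#' @export
canonical_code <- function(g) {
  aux <- mg_aux_graph(g)
  if (aux$m == 0L) return(paste0("A|", g$atoms$element[1]))
  lab <- igraph::canonical_permutation(aux$graph, colors = aux$colors)$labeling
  cg <- igraph::permute(aux$graph, lab)
  new_labels <- character(length(lab))
  new_labels[lab] <- aux$labels
  el <- igraph::as_edgelist(cg)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(aux$n, ":", aux$m, "|",
         paste(new_labels, collapse = ","), "|",
         paste(el[, 1], el[, 2], sep = "-", collapse = ";"))
}

#' Randomly reindex the atoms of a molecular graph
#'
#' Produces an isomorphic copy with atoms (and hence bonds) relabelled by a
#' permutation. Used by property tests of order-invariance.
#'
#' @param g a `mol_graph`.
#' @param perm permutation of `seq_len(n_atoms(g))`; random if omitted.
#' @return a `mol_graph`.
#' @export
permute_atoms <- function(g, perm = sample(n_atoms(g))) {
  stopifnot(length(perm) == n_atoms(g), all(sort(perm) == seq_len(n_atoms(g))))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  atoms <- data.frame(element = g$atoms$element[inv])
  bonds <- g$bonds
  if (nrow(bonds) > 0L) {
    bonds$a1 <- perm[bonds$a1]; bonds$a2 <- perm[bonds$a2]
    bonds <- bonds[sample(nrow(bonds)), , drop = FALSE]
  }
  mol_graph(atoms, bonds, name = g$name, source_format = g$source_format,
            formula = g$formula)
}
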