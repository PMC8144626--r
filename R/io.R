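#' Read an MDL molfile (V2000) into a molecular graph
#'
#' Parses a connection table with ChemmineR, kekulizes aromatic (order-4)
#' bonds through Open Babel so every bond carries a concrete order, drops
#' explicit hydrogens and formal charges from the assembly graph, and keeps
#' the full molecular formula (implicit hydrogens included) for mass
#' accounting. Multi-component records are rejected: the assembly index of
#' a mixture record is undefined.
#'
#' @param text molfile content as a single string / character vector of
#'   lines, or a path to a `.mol` file.
#' @param name optional molecule name (defaults to the molfile title line).
#' @return a `mol_graph`.
#' @export
read_molfile <- function(text, name = NULL) {
  lines <- .as_lines(text)
  if (length(lines) < 4L)
    stop("malformed molfile: fewer than 4 lines (no counts line)")
  counts_line <- lines[4L]
  if (grepl("V3000", counts_line, fixed = TRUE))
    stop("V3000 connection tables are not supported; please export as V2000")
  na <- suppressWarnings(as.integer(substr(counts_line, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts_line, 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L)
    stop("malformed counts line (line 4): ", sQuote(trimws(counts_line)))
  if (length(lines) < 4L + na + nb)
    stop(sprintf("malformed molfile: atom/bond block truncated (expected %d atom + %d bond lines after line 4)",
                 na, nb))

  ttl <- if (!is.null(name)) name else trimws(lines[1L])
  if (nb == 0L) {
    # Single-heavy-atom records; element field is columns 32-34 of the
    # atom block (V2000 fixed width).
    at_lines <- lines[5:(4L + na)]
    elements <- trimws(substr(at_lines, 32L, 34L))
    if (any(!nzchar(elements)))
      stop(sprintf("malformed atom block (line %d): empty element field",
                   4L + which(!nzchar(elements))[1]))
    formula <- .ob_formula(lines)
    heavy <- elements[elements != "H"]
    if (length(heavy) == 0L)
      stop("molecule has no heavy atoms after hydrogen suppression")
    if (is.null(formula)) {
      counts <- table(elements)
      formula <- as_formula(stats::setNames(as.integer(counts), names(counts)))
    }
    return(mol_graph(atoms = data.frame(element = heavy), bonds = NULL,
                     name = ttl, source_format = "molfile",
                     formula = formula))
  }
  parsed <- .parse_ctab(lines, kekulize = TRUE)
  .build_mol_graph(parsed, lines, name = ttl, source_format = "molfile")
}

# Hydrogen-complete molecular formula via Open Babel; NULL on failure.
.ob_formula <- function(lines) {
  lines <- lines[!grepl("^\\$\\$\\$\\$", lines)]
  txt <- paste(c(lines, "$$$$", ""), collapse = "\n")
  tryCatch({
    res <- ChemmineOB::forEachMol("SDF", txt,
                                  function(m) ChemmineOB::prop_OB(m))
    f <- res[[1]]$formula
    if (is.null(f) || !nzchar(f)) NULL else parse_formula_string(f)
  }, error = function(e) NULL)
}

.as_lines <- function(text) {
  if (length(text) > 1L) return(as.character(text))
  if (!grepl("\n", text, fixed = TRUE) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  strsplit(text, "\n", fixed = TRUE)[[1]]
}

# Parse a single molfile record (character lines) with ChemmineR; if the
# bond block contains aromatic (order 4) bonds, round-trip through Open
# Babel, which assigns a Kekule structure.
.parse_ctab <- function(lines, kekulize = TRUE) {
  sdf <- .lines_to_sdfset(lines)
  bb <- ChemmineR::bondblock(sdf[[1]])
  if (kekulize && nrow(bb) > 0L && any(bb[, 3] == 4)) {
    kek <- tryCatch({
      out <- ChemmineOB::convertFormat("MOL", "MOL",
                                       paste(lines, collapse = "\n"))
      klines <- .as_lines(out)
      ksdf <- .lines_to_sdfset(klines)
      kbb <- ChemmineR::bondblock(ksdf[[1]])
      if (nrow(kbb) > 0L && any(kbb[, 3] == 4)) NULL else ksdf
    }, error = function(e) NULL)
    if (is.null(kek)) {
      warning("kekulization failed; aromatic bond orders retained")
    } else {
      sdf <- kek
    }
  }
  sdf
}

.lines_to_sdfset <- function(lines) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  writeLines(lines, tf)
  sdf <- tryCatch(ChemmineR::read.SDFset(tf),
                  error = function(e) stop("molfile parse error: ",
                                           conditionMessage(e)))
  if (length(sdf) < 1L) stop("molfile parse error: no record found")
  sdf
}

# SDFset (single record) -> mol_graph, suppressing hydrogens and keeping
# the hydrogen-complete formula (computed from the original record lines).
.build_mol_graph <- function(sdf, lines, name, source_format) {
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  formula <- .ob_formula(lines)

  heavy <- which(elements != "H")
  if (length(heavy) == 0L)
    stop("molecule has no heavy atoms after hydrogen suppression")
  if (is.null(formula)) {
    counts <- table(elements)
    formula <- as_formula(stats::setNames(as.integer(counts), names(counts)))
  }
  map <- match(seq_along(elements), heavy)  # old index -> heavy index

  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- NULL
  } else {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
    keep <- elements[a1] != "H" & elements[a2] != "H"
    a1 <- map[a1[keep]]; a2 <- map[a2[keep]]; ord <- ord[keep]
    if (any(!ord %in% 1:4))
      stop("unsupported bond order code(s): ",
           paste(unique(ord[!ord %in% 1:4]), collapse = ", "))
    bonds <- data.frame(a1 = a1, a2 = a2,
                        order = .bond_orders[ord])
  }
  mol_graph(atoms = data.frame(element = elements[heavy]), bonds = bonds,
            name = name, source_format = source_format, formula = formula)
}

#' Read an SDF file into a list of molecular graphs
#'
#' Splits the `$$$$`-delimited stream into records and parses each like
#' [read_molfile()]. Unparseable records are skipped with a message rather
#' than aborting the batch.
#'
#' @param path path to an SDF file, or its content as a string.
#' @return list of `mol_graph` (possibly empty).
#' @export
read_sdf <- function(path) {
  lines <- .as_lines(path)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    rec <- lines[starts[i]:ends[i]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (all(!nzchar(trimws(rec)))) next
    g <- tryCatch(read_molfile(rec),
                  error = function(e) {
                    message(sprintf("skipping SDF record %d: %s", i,
                                    conditionMessage(e)))
                    NULL
                  })
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

#' Read a SMILES string into a molecular graph
#'
#' Converts through Open Babel (which kekulizes aromatic rings) and applies
#' the same normalization as [read_molfile()].
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule name.
#' @return a `mol_graph`.
#' @export
read_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL", paste0(smiles, "\n")),
    error = function(e) "")
  lines <- .as_lines(mol)
  if (length(lines) < 4L || !nzchar(paste(trimws(lines), collapse = "")))
    stop("invalid SMILES: ", sQuote(smiles))
  read_molfile(lines, name = name)
}

#' Write a molecular graph as an MDL molfile (V2000)
#'
#' Connectivity-only output: coordinates are written as zeros and
#' suppressed hydrogens are not restored.
#'
#' @param g a `mol_graph`.
#' @param path optional output path; when `NULL` the text is returned.
#' @return the molfile text, invisibly when written to `path`.
#' @export
write_molfile <- function(g, path = NULL) {
  stopifnot(inherits(g, "mol_graph"))
  na <- n_atoms(g); nb <- n_bonds(g)
  ord_num <- match(g$bonds$order, .bond_orders)
  lines <- c(
    g$name,
    "  massembly",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$atoms$element),
    if (nb > 0L) sprintf("%3d%3d%3d  0", g$bonds$a1, g$bonds$a2, ord_num),
    "M  END"
  )
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(c(lines), path)
  invisible(txt)
}

#' Write a list of molecular graphs as an SDF file
#'
#' @param graphs list of `mol_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    writeLines(write_molfile(g), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}
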