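#' @title Split-branch molecular assembly index
#' @description The molecular assembly index (MA) of a molecule is the
#' length of the shortest assembly pathway that builds it from bonds, where
#' any fragment constructed along the way can be reused. Finding the true
#' minimum is combinatorially hard; the split-branch algorithm computes an
#' upper bound by partitioning the molecule's bonds into classes of
#' identical (isomorphic) substructures and scoring
#' \deqn{MA = \sum_i (MA_i + N_i - 1)}
#' over the chosen partition, where \eqn{MA_i} is the (recursively
#' computed) index of the i-th duplicated fragment and \eqn{N_i} the number
#' of its edge-disjoint copies; a single bond scores 1.
#'
#' Partitions are searched exhaustively for molecules with at most
#' `exhaustive_limit` bonds and by a greedy largest-savings-first strategy
#' (recursing on fragments and on the remainder, memoized by canonical
#' code) above that, so the result is deterministic for a given input
#' regardless of atom ordering.
#'
#' @param g a [mol_graph()] with at least one bond.
#' @param convention `"eq1"` (single bond scores 1, the default) or
#'   `"joins"` (number of joining operations, i.e. the eq1 value minus 1).
#' @param exhaustive_limit exhaustive partition search is used when the
#'   bond count is at most this (default 10).
#' @param max_fragment_bonds cap on the size of duplicated fragments
#'   considered; defaults to half the bond count (a duplicate needs two
#'   copies).
#' @param timeout wall-clock limit in seconds; on expiry the naive bond
#'   count is returned with `partial = TRUE` and a warning.
#' @return An `assembly_result`: list with elements `ma`, `convention`,
#'   `partition_tree`, `is_upper_bound` (always `TRUE`), `partial`.
#' @seealso [exact_ma()] for the brute-force oracle on small graphs.
#' @export
split_branch_ma <- function(g, convention = c("eq1", "joins"),
                            exhaustive_limit = 10, max_fragment_bonds = NULL,
                            timeout = Inf) {
  stopifnot(inherits(g, "mol_graph"))
  convention <- match.arg(convention)
  m <- n_bonds(g)
  if (m == 0L) {
    warning("zero-bond graph: assembly index defined as 0")
    return(.assembly_result(0L, convention, NULL, partial = FALSE))
  }
  env <- new.env(parent = emptyenv())
  env$frag_cache <- new.env(parent = emptyenv())
  env$exhaustive_limit <- exhaustive_limit
  env$max_fragment_bonds <- max_fragment_bonds

  compute <- function() {
    part <- .partition_search(g, seq_len(m), env)
    .assembly_result(part$cost, convention, part, partial = FALSE)
  }
  if (is.finite(timeout)) {
    res <- tryCatch({
      setTimeLimit(elapsed = timeout, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
      compute()
    }, error = function(e) {
      if (grepl("elapsed time limit", conditionMessage(e))) {
        warning(sprintf("assembly search timed out after %gs; returning naive bond count", timeout))
        .assembly_result(m, convention, NULL, partial = TRUE)
      } else stop(e)
    })
    return(res)
  }
  compute()
}

.assembly_result <- function(ma_eq1, convention, partition, partial) {
  ma <- if (convention == "joins") max(ma_eq1 - 1L, 0L) else as.integer(ma_eq1)
  structure(list(ma = as.integer(ma), convention = convention,
                 partition_tree = partition, is_upper_bound = TRUE,
                 partial = partial),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> MA = %d (%s convention%s)\n", x$ma,
              x$convention,
              if (isTRUE(x$partial)) ", PARTIAL: search timed out" else ""))
  if (!is.null(x$partition_tree) && length(x$partition_tree$classes)) {
    for (cl in x$partition_tree$classes)
      cat(sprintf("  class: %d-bond fragment x%d (MA_i = %d)\n",
                  n_bonds(cl$fragment), cl$multiplicity, cl$ma_fragment))
    if (length(x$partition_tree$singletons))
      cat(sprintf("  + %d singleton bond(s)\n",
                  length(x$partition_tree$singletons)))
  }
  invisible(x)
}

# ---- connected edge-subset enumeration (ESU on the line graph) ----------

# Neighbour lists of edges sharing an atom, restricted to `within`.
.edge_adjacency <- function(g, within) {
  m <- n_bonds(g)
  adj <- vector("list", m)
  ends <- cbind(g$bonds$a1, g$bonds$a2)
  inset <- logical(m); inset[within] <- TRUE
  by_atom <- split(rep(within, 2L), c(ends[within, 1], ends[within, 2]))
  for (at in by_atom) {
    for (e in at) adj[[e]] <- c(adj[[e]], setdiff(at, e))
  }
  lapply(adj, function(x) sort(unique(x)))
}

# All connected subsets of `within` (edge indices of g) with sizes in
# 1..max_size, each enumerated exactly once.
connected_edge_subsets <- function(g, max_size, within = seq_len(n_bonds(g))) {
  adj <- .edge_adjacency(g, within)
  out <- vector("list", 0L)
  emit <- function(s) out[[length(out) + 1L]] <<- s
  for (root in within) {
    rec <- function(S, ext, nbhd) {
      emit(S)
      if (length(S) == max_size) return()
      while (length(ext) > 0L) {
        w <- ext[1L]; ext <- ext[-1L]
        new_nb <- adj[[w]]
        excl <- new_nb[new_nb > root & !(new_nb %in% nbhd) & !(new_nb %in% S)]
        rec(c(S, w), c(ext, excl), union(nbhd, new_nb))
      }
    }
    nb0 <- adj[[root]]
    rec(root, nb0[nb0 > root], union(root, nb0))
  }
  out
}

# Canonical shape code of an edge subset; cheap special case for 1 bond.
.subset_code <- function(g, idx, labels) {
  if (length(idx) == 1L) return(paste0("B|", labels[idx]))
  canonical_code(fragment_graph(g, idx))
}

#' Enumerate duplicated substructures of a molecule
#'
#' Finds all connected fragment shapes (up to isomorphism, up to
#' `max_fragment_bonds` bonds) that occur at least twice as pairwise
#' edge-disjoint embeddings; copies may share atoms, since joining
#' operations glue fragments at atoms while bonds are the conserved units.
#'
#' @param g a [mol_graph()].
#' @param max_fragment_bonds size cap; defaults to half the bond count.
#' @param within internal: restrict to a subset of bond indices.
#' @return list of duplicate classes, largest fragment first (ties broken
#'   by canonical code); each class is a list with `fragment` (a
#'   `mol_graph`), `code`, `embeddings` (list of bond-index vectors),
#'   `packing` (the chosen edge-disjoint copies) and `multiplicity`.
#' @export
enumerate_duplicate_classes <- function(g, max_fragment_bonds = NULL,
                                        within = seq_len(n_bonds(g))) {
  n_in <- length(within)
  if (n_in < 2L) return(list())
  cap <- max(1L, floor(n_in / 2))
  if (!is.null(max_fragment_bonds)) cap <- min(cap, max_fragment_bonds)
  labels <- bond_labels(g)
  subsets <- connected_edge_subsets(g, cap, within)
  codes <- vapply(subsets, function(s) .subset_code(g, s, labels), "")
  groups <- split(seq_along(subsets), codes)
  classes <- list()
  for (code in names(groups)) {
    embs <- subsets[groups[[code]]]
    if (length(embs) < 2L) next
    embs <- embs[order(vapply(embs, function(s) paste(sort(s), collapse = ","), ""))]
    packing <- .greedy_packing(embs)
    if (length(packing) < 2L) next
    classes[[length(classes) + 1L]] <- list(
      fragment = fragment_graph(g, embs[[1L]]),
      code = code,
      size = length(embs[[1L]]),
      embeddings = embs,
      packing = packing,
      multiplicity = length(packing))
  }
  if (length(classes) == 0L) return(classes)
  ord <- order(-vapply(classes, `[[`, 0L, "size"),
               vapply(classes, `[[`, "", "code"))
  classes[ord]
}

# Deterministic greedy maximum edge-disjoint packing of embeddings
# (embeddings assumed sorted lexicographically).
.greedy_packing <- function(embs) {
  used <- integer(0)
  packing <- list()
  for (e in embs) {
    if (!any(e %in% used)) {
      packing[[length(packing) + 1L]] <- e
      used <- c(used, e)
    }
  }
  packing
}

# ---- partition search ----------------------------------------------------

# Split-branch MA of a standalone fragment, memoized by canonical code.
.sb_ma_fragment <- function(frag, env) {
  code <- canonical_code(frag)
  hit <- env$frag_cache[[code]]
  if (!is.null(hit)) return(hit)
  m <- n_bonds(frag)
  val <- if (m == 1L) 1L else .partition_search(frag, seq_len(m), env)$cost
  env$frag_cache[[code]] <- val
  val
}

# Minimal partition of `edges` (bond indices of g) into duplicate classes
# and singletons. Exhaustive for small edge sets, greedy otherwise.
.partition_search <- function(g, edges, env) {
  if (length(edges) <= env$exhaustive_limit) {
    ctx <- list(memo = new.env(parent = emptyenv()),
                labels = bond_labels(g))
    .partition_exhaustive(g, sort(edges), env, ctx)
  } else {
    .partition_greedy(g, sort(edges), env)
  }
}

.partition_exhaustive <- function(g, edges, env, ctx) {
  if (length(edges) == 0L) return(list(cost = 0L, classes = list(), singletons = integer()))
  key <- paste(edges, collapse = ",")
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)

  e <- edges[1L]
  # option 1: e stands alone (every all-singleton completion is covered
  # by recursion; grouping identical single bonds gives the same cost)
  rest <- .partition_exhaustive(g, edges[-1L], env, ctx)
  best <- list(cost = 1L + rest$cost, classes = rest$classes,
               singletons = c(e, rest$singletons))

  # option 2: e lies inside a duplicated multi-bond (or single-bond,
  # multiplicity >= 2) fragment class
  cap <- floor(length(edges) / 2)
  if (!is.null(env$max_fragment_bonds)) cap <- min(cap, env$max_fragment_bonds)
  if (cap >= 1L) {
    subsets <- connected_edge_subsets(g, cap, edges)
    codes <- vapply(subsets, function(s) .subset_code(g, s, ctx$labels), "")
    with_e <- which(vapply(subsets, function(s) e %in% s, TRUE))
    for (i in with_e) {
      s0 <- subsets[[i]]
      mates <- which(codes == codes[i])
      mates <- mates[vapply(subsets[mates],
                            function(s) !any(s %in% s0), TRUE)]
      if (length(mates) == 0L) next
      ma_i <- .sb_ma_fragment(fragment_graph(g, s0), env)
      # enumerate every packing {s0} + >=1 disjoint later copies
      packs <- .enumerate_packings(subsets, mates)
      for (p in packs) {
        copies <- c(list(s0), subsets[p])
        covered <- unlist(copies)
        n_i <- length(copies)
        rem <- .partition_exhaustive(g, setdiff(edges, covered), env, ctx)
        cost <- ma_i + n_i - 1L + rem$cost
        if (cost < best$cost) {
          cl <- list(fragment = fragment_graph(g, s0), code = codes[i],
                     size = length(s0), multiplicity = n_i,
                     copies = copies, ma_fragment = ma_i)
          best <- list(cost = cost, classes = c(list(cl), rem$classes),
                       singletons = rem$singletons)
        }
      }
    }
  }
  ctx$memo[[key]] <- best
  best
}

# All non-empty sets of pairwise-disjoint embeddings drawn from `mates`
# (indices into `subsets`), in increasing index order.
.enumerate_packings <- function(subsets, mates) {
  out <- list()
  rec <- function(chosen, used, remaining) {
    if (length(chosen)) out[[length(out) + 1L]] <<- chosen
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      if (!any(subsets[[j]] %in% used)) {
        rec(c(chosen, j), c(used, subsets[[j]]),
            remaining[-seq_len(k)])
      }
    }
  }
  rec(integer(0), integer(0), mates)
  out
}

.partition_greedy <- function(g, edges, env) {
  # above the exhaustive regime, duplicated fragments are searched up to
  # 10 bonds by default (configurable via max_fragment_bonds): subset
  # enumeration is exponential in the fragment-size cap
  cap <- if (is.null(env$max_fragment_bonds)) 10L else env$max_fragment_bonds
  classes <- list()
  remaining <- edges
  repeat {
    if (length(remaining) < 2L) break
    cand <- enumerate_duplicate_classes(g, cap, within = remaining)
    if (length(cand) == 0L) break
    best <- NULL; best_sav <- 0L
    for (cl in cand) {
      ma_i <- .sb_ma_fragment(cl$fragment, env)
      sav <- cl$multiplicity * cl$size - (ma_i + cl$multiplicity - 1L)
      if (sav > best_sav) {
        best <- cl; best$ma_fragment <- ma_i; best_sav <- sav
      }
    }
    if (is.null(best)) break
    best$copies <- best$packing
    classes[[length(classes) + 1L]] <- best
    remaining <- setdiff(remaining, unlist(best$packing))
  }
  cost <- length(remaining) +
    sum(vapply(classes, function(cl) cl$ma_fragment + cl$multiplicity - 1L, 0L))
  list(cost = as.integer(cost), classes = classes, singletons = remaining)
}

#' Choose a minimal-cost duplicate partition of a molecule
#'
#' Returns the partition of the molecule's bonds into duplicated fragment
#' classes plus singleton bonds that minimizes
#' \eqn{\sum_i (MA_i + N_i - 1)} among those explored: all partitions when
#' the bond count is at most `exhaustive_limit`, a greedy
#' largest-savings-first search above it.
#'
#' @inheritParams split_branch_ma
#' @return list with `cost`, `classes`, `singletons`.
#' @export
choose_partition <- function(g, exhaustive_limit = 10,
                             max_fragment_bonds = NULL) {
  stopifnot(inherits(g, "mol_graph"), n_bonds(g) >= 1L)
  env <- new.env(parent = emptyenv())
  env$frag_cache <- new.env(parent = emptyenv())
  env$exhaustive_limit <- exhaustive_limit
  env$max_fragment_bonds <- max_fragment_bonds
  .partition_search(g, seq_len(n_bonds(g)), env)
}

# ---- chemical-space survey ----------------------------------------------

#' Survey assembly index against molecular mass
#'
#' Computes the split-branch MA and average mass of each molecule and
#' tabulates, per mass bin, the normalized frequency of each MA value
#' (frequencies sum to one within a bin).
#'
#' @param molecules list of [mol_graph()].
#' @param bin_width mass bin width in Daltons (default 50).
#' @param ... passed to [split_branch_ma()].
#' @return data.frame with columns `bin_low`, `bin_high`, `ma`, `count`,
#'   `frequency`.
#' @export
survey_ma_vs_mass <- function(molecules, bin_width = 50, ...) {
  if (length(molecules) == 0L)
    return(data.frame(bin_low = numeric(), bin_high = numeric(),
                      ma = integer(), count = integer(),
                      frequency = numeric()))
  mass <- vapply(molecules, function(g) average_mass(molecular_formula(g)), 0)
  ma <- vapply(molecules, function(g) split_branch_ma(g, ...)$ma, 0L)
  bin <- floor(mass / bin_width) * bin_width
  tab <- as.data.frame(table(bin = bin, ma = ma), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab$bin <- as.numeric(tab$bin); tab$ma <- as.integer(tab$ma)
  per_bin <- stats::ave(tab$Freq, tab$bin, FUN = sum)
  out <- data.frame(bin_low = tab$bin, bin_high = tab$bin + bin_width,
                    ma = tab$ma, count = tab$Freq,
                    frequency = tab$Freq / per_bin)
  out <- out[order(out$bin_low, out$ma), , drop = FALSE]
  rownames(out) <- NULL
  out
}
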