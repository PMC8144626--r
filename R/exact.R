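#' Exact assembly index by exhaustive pathway search (small graphs)
#'
#' Realizes the definition of the assembly index literally: the smallest
#' number of joining operations that constructs the molecule starting from
#' its bonds, where every fragment built along the way remains available
#' for reuse. A joining operation glues two available fragments by
#' identifying atoms of matching elements; the search assumes that every
#' intermediate on a minimal pathway is (isomorphic to) a connected
#' subgraph of the target, so the state space is the set of target
#' subgraph shapes.
#'
#' The search is iterative deepening over the number of joins, with a
#' doubling bound (a join at most doubles the largest available fragment)
#' and failure memoization. It is exponential and therefore refused above
#' `bond_limit` bonds. Used as the verification oracle for
#' [split_branch_ma()], which can never return less.
#'
#' @param g a [mol_graph()] with at least one bond.
#' @param bond_limit refuse graphs with more bonds than this (default 8).
#' @return integer assembly index in the eq1 convention (minimal joins + 1).
#' @export
exact_ma <- function(g, bond_limit = 8) {
  stopifnot(inherits(g, "mol_graph"))
  m <- n_bonds(g)
  if (m < 1L) stop("exact_ma needs at least one bond")
  if (m > bond_limit)
    stop(sprintf("graph has %d bonds; exact search is limited to %d (combinatorial blow-up)",
                 m, bond_limit))
  if (m == 1L) return(1L)

  sp <- .shape_space(g)
  target <- sp$shape_of_mask[sp$full_mask]
  basics <- sort(unique(sp$shape_of_mask[sp$masks[sp$sizes == 1L]]))
  jt <- .join_table(sp)

  lb <- max(1L, as.integer(ceiling(log2(m))))
  failed <- new.env(parent = emptyenv())
  for (depth in lb:(m - 1L)) {
    if (.assembly_dfs(basics, depth, target, m, sp, jt, failed))
      return(depth + 1L)
  }
  m  # unreachable: sequential bond addition always succeeds at m - 1 joins
}

# Enumerate connected edge subsets of g as bitmasks; map each to a shape
# id via canonical codes.
.shape_space <- function(g) {
  m <- n_bonds(g)
  ends <- cbind(g$bonds$a1, g$bonds$a2)
  labels <- bond_labels(g)
  masks <- integer(0); sizes <- integer(0)
  codes_by_mask <- character(0)
  all_masks <- seq_len(bitwShiftL(1L, m) - 1L)
  connected <- logical(length(all_masks))
  shape_of_mask <- integer(length(all_masks))
  code_tab <- new.env(parent = emptyenv())
  shape_bonds <- integer(0)
  next_id <- 0L
  for (mask in all_masks) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (!.edges_connected(ends, idx)) next
    connected[mask] <- TRUE
    code <- if (length(idx) == 1L) paste0("B|", labels[idx]) else
      canonical_code(fragment_graph(g, idx))
    id <- code_tab[[code]]
    if (is.null(id)) {
      next_id <- next_id + 1L
      id <- next_id
      code_tab[[code]] <- id
      shape_bonds[id] <- length(idx)
    }
    masks <- c(masks, mask); sizes <- c(sizes, length(idx))
    shape_of_mask[mask] <- id
  }
  list(m = m, masks = masks, sizes = sizes, connected = connected,
       shape_of_mask = shape_of_mask, shape_bonds = shape_bonds,
       full_mask = bitwShiftL(1L, m) - 1L, ends = ends)
}

.edges_connected <- function(ends, idx) {
  if (length(idx) <= 1L) return(TRUE)
  at <- unique(as.vector(ends[idx, , drop = FALSE]))
  parent <- seq_along(at)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in idx) {
    i <- find(match(ends[e, 1], at)); j <- find(match(ends[e, 2], at))
    if (i != j) parent[i] <- j
  }
  length(unique(vapply(seq_along(at), find, 0L))) == 1L
}

# For every connected mask, every split into two connected edge-disjoint
# parts is a feasible join (the parts share at least one atom in the
# parent, and a join may identify any matching atom set, which is what
# guarantees the split-branch value is attainable as a pathway).
.join_table <- function(sp) {
  jt <- new.env(parent = emptyenv())
  for (u in sp$masks[sp$sizes >= 2L]) {
    s <- bitwAnd(u - 1L, u)
    while (s > 0L) {
      comp <- bitwAnd(u, bitwNot(s))
      if (s <= comp && comp > 0L && sp$connected[s] && sp$connected[comp]) {
        a <- sp$shape_of_mask[s]; b <- sp$shape_of_mask[comp]
        key <- paste0(min(a, b), "|", max(a, b))
        res <- jt[[key]]
        tgt <- sp$shape_of_mask[u]
        if (is.null(res)) jt[[key]] <- tgt
        else if (!(tgt %in% res)) jt[[key]] <- c(res, tgt)
      }
      s <- bitwAnd(s - 1L, u)
    }
  }
  jt
}

.assembly_dfs <- function(avail, remaining, target, m, sp, jt, failed) {
  # everything producible in one join from the available shapes
  prod <- integer(0)
  na <- length(avail)
  for (i in seq_len(na)) for (j in i:na) {
    key <- paste0(avail[i], "|", avail[j])
    r <- jt[[key]]
    if (!is.null(r)) prod <- c(prod, r)
  }
  prod <- setdiff(unique(prod), avail)
  if (target %in% prod) return(TRUE)
  if (remaining <= 1L) return(FALSE)
  maxb <- max(sp$shape_bonds[avail])
  if (maxb * 2^remaining < m) return(FALSE)

  key <- paste(avail, collapse = ",")
  prev <- failed[[key]]
  if (!is.null(prev) && prev >= remaining) return(FALSE)

  prod <- prod[order(-sp$shape_bonds[prod])]
  for (c_new in prod) {
    if (.assembly_dfs(sort(c(avail, c_new)), remaining - 1L, target,
                      m, sp, jt, failed))
      return(TRUE)
  }
  failed[[key]] <- max(remaining, if (is.null(prev)) 0L else prev)
  FALSE
}
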