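#' Configuration for the weighted-tree chance-formation model
#'
#' The chance of a molecule of assembly index L forming in an unconstrained
#' process is modelled as the probability of the most likely length-L path
#' through a random weighted tree. The root is the pool of bonds; a node at
#' depth l has `max(2, round(c * l^alpha))` outgoing edges (the number of
#' possible products grows with depth, since previously made fragments can
#' be reused), and each edge weight is drawn as `10^U(0, h)` and normalized
#' so the outgoing probabilities of a node sum to one.
#'
#' @param alpha growth exponent of the branching factor; 2 (conservative,
#'   quadratic) to 3 (super-linear limiting case) spans the model range.
#' @param h orders of magnitude over which edge weights vary (default 4,
#'   reflecting relative reaction rates spanning four orders of magnitude).
#' @param c proportionality constant of the branching law (default 1).
#' @param max_depth maximum path length L to evaluate.
#' @param n_trees number of independent trees to sample.
#' @param seed integer RNG seed; each tree uses its own stream derived from
#'   `(seed, tree index)`, so results are reproducible and independent of
#'   evaluation order.
#' @return a `tree_config` list.
#' @export
tree_config <- function(alpha = 2, h = 4, c = 1, max_depth = 30,
                        n_trees = 1000, seed = 1) {
  stopifnot(alpha >= 0, h >= 0, c > 0, max_depth >= 1, n_trees >= 1)
  structure(list(alpha = alpha, h = h, c = c,
                 max_depth = as.integer(max_depth),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "tree_config")
}

#' Branching factor at a given depth
#'
#' `k = max(2, round(c * l^alpha))`: the number of outgoing edges of a node
#' at depth `l`, floored at two so every step is a genuine choice.
#'
#' @param l depth (vectorized), `l >= 1`.
#' @param cfg a [tree_config()].
#' @return integer vector of branching factors.
#' @export
branching_size <- function(l, cfg) {
  stopifnot(all(l >= 1))
  as.integer(pmax(2, round(cfg$c * l^cfg$alpha)))
}

#' Probability of the most likely edge out of a node
#'
#' Draws `k` weights from `10^U(0, h)`, normalizes them to sum to one, and
#' returns the largest: the transition probability a greedy walker takes.
#' With `h = 0` all weights are equal and the value is exactly `1/k`.
#'
#' @param k number of outgoing edges.
#' @param cfg a [tree_config()] (only `h` is used).
#' @return probability in (0, 1].
#' @export
sample_step <- function(k, cfg) {
  stopifnot(k >= 1)
  if (k == 1L) return(1)
  w <- 10^stats::runif(k, 0, cfg$h)
  max(w) / sum(w)
}

# Deterministic per-tree substream: keep derived seeds below 2^31.
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + index * 7919) %% 2147483629) + 1L
}

#' Sample one weighted tree and walk its most likely path
#'
#' For each depth `l = 1..max_depth`, draws the outgoing edge weights of
#' the current node and follows the most probable edge (greedy per-level
#' maximization; the global optimum over an astronomically large tree is
#' approximated by taking the maximum over many sampled trees). The
#' cumulative path probability is accumulated in log10 space to avoid
#' underflow.
#'
#' @param cfg a [tree_config()].
#' @param tree_index index of the tree, used to derive its RNG stream.
#' @return a `path_sample`: list with `step_probabilities`,
#'   `cumulative_log10` and `cumulative` (linear scale, may underflow to 0).
#' @export
sample_tree <- function(cfg, tree_index = 1L) {
  stopifnot(inherits(cfg, "tree_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.derive_seed(cfg$seed, tree_index))
  ks <- branching_size(seq_len(cfg$max_depth), cfg)
  steps <- vapply(ks, sample_step, 0, cfg = cfg)
  lg <- cumsum(log10(steps))
  structure(list(step_probabilities = steps, cumulative_log10 = lg,
                 cumulative = 10^lg),
            class = "path_sample")
}

#' Chance-formation curve: maximum path probability vs path length
#'
#' Samples `cfg$n_trees` weighted trees and records, per depth, the largest
#' most-likely-path probability seen in any tree. Because the maximum over
#' trees can only grow with the number of trees, a curve computed from
#' fewer trees is a conservative (lower) estimate of the bound.
#'
#' @param cfg a [tree_config()].
#' @return a `chance_curve` data.frame with columns `depth`,
#'   `max_log10_prob`, `max_prob`, and the configuration in attributes.
#' @export
chance_curve <- function(cfg) {
  stopifnot(inherits(cfg, "tree_config"))
  best <- rep(-Inf, cfg$max_depth)
  for (i in seq_len(cfg$n_trees)) {
    lg <- sample_tree(cfg, i)$cumulative_log10
    upd <- lg > best
    best[upd] <- lg[upd]
  }
  out <- data.frame(depth = seq_len(cfg$max_depth),
                    max_log10_prob = best,
                    max_prob = 10^best)
  attr(out, "config") <- cfg
  class(out) <- c("chance_curve", "data.frame")
  out
}

#' Reference abundance ratios for reading the chance curve
#'
#' Four labelled comparison lines: one star in the Milky Way (1e-11), one
#' gram out of Earth's biomass (1e-17), one molecule in a mole (1e-23), and
#' one gram out of Earth's mass (1e-29).
#'
#' @return named numeric vector of probabilities.
#' @export
reference_thresholds <- function() {
  c("one star in the milky way" = 1e-11,
    "one gram of Earth's biomass" = 1e-17,
    "one in a mole" = 1e-23,
    "one gram of Earth's mass" = 1e-29)
}
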