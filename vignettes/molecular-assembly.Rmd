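---
title: "Molecular assembly: the model behind massembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular assembly: the model behind massembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massembly)
```

## The object being scored

`massembly` scores molecules on the molecular assembly index (MA): the
length of the shortest sequence of joining operations that constructs
the molecule from its bonds, where every intermediate fragment, once
built, can be reused at no further structural cost. The index is a
property of labelled connectivity alone. A molecule is therefore
reduced to a hydrogen-suppressed graph: atoms carry an element symbol,
bonds carry an order (`single`/`double`/`triple`), and two bonds are
*identical* exactly when their sorted endpoint elements and order
agree. Three normalization choices define this object:

* **Hydrogens and formal charges are dropped** from the assembly graph
  (they are retained in the formula, so masses are correct). Counting
  C–H bonds would mostly re-measure molecular size; the heavy-atom
  skeleton is where structural specificity lives.
* **Aromatic bonds are kekulized on input** (through Open Babel), so
  every bond has a concrete order. "Identical bonds" needs a
  deterministic label; a delocalized order would make bond equality
  ill-defined. If kekulization fails the aromatic order is retained
  with a warning.
* **Multi-component records are rejected.** The MA of a mixture record
  is undefined; each component must be scored on its own.

Stereochemistry is out of scope throughout: stereocenter counts enter
only through `diastereomer_count(n) = 2^n`, as user input.

## The split-branch upper bound

The exact index is a shortest-path question in an enormous implicit
graph, so the package computes the *split-branch* value: partition the
molecule's bonds into classes of mutually isomorphic, pairwise
edge-disjoint connected substructures, and score

$$MA = \sum_i \left( MA_i + N_i - 1 \right),$$

with $MA = 1$ for a single bond. Each class is paid for by building its
fragment once ($MA_i$, computed by the same algorithm recursively) and
then joining one extra copy per duplicate ($N_i - 1$). Any such
partition corresponds to a realizable pathway, so the minimum over the
partitions searched is an upper bound on the true MA; `is_upper_bound`
is always `TRUE` on results.

Design choices where the design was genuinely open:

* **Base case.** The recursion's printed form assigns a single bond
  MA = 1, while the verbal definition (number of joining operations)
  would give 0. We implement the equation as the operational definition
  (`convention = "eq1"`, the default) and expose
  `convention = "joins"` (= eq1 − 1) for comparability with later
  assembly-theory literature.
* **Search strategy.** All bond-set partitions are searched exhaustively
  (with memoization on edge subsets) for molecules of at most
  `exhaustive_limit = 10` bonds. Above that, a greedy strategy
  repeatedly takes the duplicate class with the largest saving
  $N_i \cdot |F_i| - (MA_i + N_i - 1)$, recursing on the fragment and
  the remainder; fragments are memoized by canonical code and ties are
  broken by canonical-code order, so results are deterministic and
  independent of atom numbering. In the greedy regime duplicated
  fragments are searched up to 10 bonds by default
  (`max_fragment_bonds`), because connected-subgraph enumeration is
  exponential in that cap.
* **Copies share atoms, not bonds.** Joining superimposes atoms, so
  atoms are the glue and bonds the conserved units; edge-disjointness is
  the right notion of "duplicate".
* **Timeout.** High-complexity molecules can exhaust any search budget;
  `timeout` returns the naive bond count flagged `partial = TRUE`
  rather than blocking. Paclitaxel (68 heavy-atom bonds, bundled as
  `inst/extdata/taxol.mol`) exceeds the default search budget; with
  `max_fragment_bonds = 8` it scores an upper bound of 31 in seconds.

### The exact oracle

`exact_ma()` realizes the definition literally for graphs of up to 8
bonds: iterative-deepening search over join sequences, where a join may
glue two available fragments by identifying any matching set of atoms.
Two reductions keep it tractable, both documented assumptions: minimal
pathways are assumed to use only connected subgraphs of the target, and
a join of two fragments is modelled as any split of a target subgraph
into two connected edge-disjoint parts. The second is deliberately
general — restricting joins to single-atom (or two-atom ring-closure)
identifications would make some split-branch partitions unrealizable
and break the upper-bound guarantee; the tetrahedrane skeleton (K4) is
the smallest counterexample. Under the implemented semantics
`split_branch_ma(g) >= exact_ma(g)` holds by construction, and the test
suite verifies it on hundreds of random valence-legal molecules, with
equality on the doubling chains (2^k identical bonds, MA = k + 1).

## Chance formation as a random walk on weighted trees

To connect MA to abiotic plausibility, unconstrained assembly is
modelled as a walk from the bond pool down a random tree. At depth $l$
a node has $k = \max(2, \mathrm{round}(c\, l^{\alpha}))$ outgoing
edges: the number of reachable products grows with depth because
previously made fragments recombine. Edge weights are drawn as
$w \sim 10^{\,U(0,h)}$ and normalized per node, mimicking reaction
rates spanning $h$ orders of magnitude; the default $h = 4$. The
probability of the most likely path to depth $L$ bounds the chance that
an unconstrained process makes a *specific* MA-$L$ molecule.

Parameters, with units and defaults:

| parameter | meaning | default / range |
|---|---|---|
| `alpha` | growth exponent of branching | 2 (conservative) to 3 (limiting) |
| `h` | orders of magnitude of weight spread | 4 |
| `c` | branching proportionality constant | 1, with a floor of 2 edges |
| `max_depth` | longest path length evaluated | 30 |
| `n_trees` | trees sampled | 1000 |

Numerical and design choices:

* **Greedy per-level maximization.** The full tree has $\prod_l k(l)$
  nodes — astronomically many at depth 30 — so the "most likely path"
  is taken greedily (max-probability edge at each level), and the
  maximum over many sampled trees approximates the global optimum.
  This is an approximation, documented as such.
* **Log-space accumulation.** Path probabilities reach $10^{-60}$;
  products are accumulated as sums of $\log_{10}$, with linear values
  materialized only for display.
* **Reproducible streams.** Tree $i$ uses an RNG stream derived from
  `(seed, i)`, so curves are reproducible, parallelizable, and the
  maximum over the first $n$ trees is non-decreasing in $n$ — which is
  why a scaled-down run (10^3 trees here; the original-scale analysis
  used millions) is a *conservative* estimate of the bound.
* **Closed form at `h = 0`.** Equal weights give exactly
  $\prod_l 1/k(l)$; the tests pin the simulator to this.

At `alpha = 3, h = 4` the curve crosses one-in-a-mole ($10^{-23}$)
between depths 15 and 16 (about $10^{-22.7}$ at 15, $10^{-25.3}$ at
16), and at `alpha = 2` a 30-step molecule sits near $10^{-37}$ —
within the $10^{-35}$–$10^{-60}$ span the model yields across
$\alpha \in [2,3]$ at that depth. So "MA in the high teens and beyond"
is the regime where chance formation in detectable abundance is
excluded; the exact depth at which the one-in-a-mole line is crossed
moves by about one step across seeds and readings of the branching law.

## Measuring MA with tandem MS

High-MA molecules, having many inequivalent bonds, fragment into many
distinct MS2 peaks. The experimental pipeline is:

1. **Noise filtering** (`noise_filter()`): keep peaks with intensity at
   least `max(relative_threshold × base peak, absolute_floor)` in an
   optional m/z window. The defaults (1% of base peak, floor 0, full
   window) are the package's own operating point, recorded in every
   `peak_count` for provenance. Filtering is idempotent because the
   base peak always survives.
2. **Calibration** (`fit_calibration()`): linear quantile regression of
   computed MA on filtered peak count at τ = 0.05/0.5/0.95 — median
   prediction plus a 90% prediction band. MA is regressed *on* peak
   count so that estimating an unknown ion is direct evaluation and the
   band lives in MA units. The pinball loss is minimized exactly by
   enumerating candidate lines through pairs of observations (an
   optimal linear quantile fit passes through two points); the solver
   is deterministic. Replicate standard scans are averaged
   (arithmetic mean, unrounded) by `count_for_standard()`.
3. **Acquisition** (`dda_select()`): per MS1 survey scan, the 15 most
   intense ions in the 300–500 m/z window (where mass constrains MA
   least) are fragmented; an ion selected twice within 10 s is excluded
   for 30 s, letting lower-intensity ions through on later cycles.
4. **Verdict** (`analyze_sample()`): each MS2 scan becomes an ion MA
   estimate; the sample's MA is the *maximum* of the per-ion medians,
   compared against a threshold of 15 — the level above which, in the
   motivating survey, only samples containing biologically or
   technologically produced molecules scored. The verdict wording is
   deliberately "contains high-MA molecules" / "no high-MA molecules
   detected": low maxima do not demonstrate abiotic origin (false
   negatives are expected; false positives are what the design
   guards against). Co-isolation of near-isobaric precursors (within
   the 0.5 Th isolation width) is warned about but not corrected.

## What the synthetic data emulate — and what they do not

The package is validated end to end on generated inputs:

* `make_doubling_chain(k)`: chains of $2^k$ identical bonds with
  provably exact MA $k+1$ — the anchors of the oracle suite.
* `make_random_molecule()`: connected, valence-legal graphs grown bond
  by bond, with a duplication bias that spreads achieved MA.
* `make_spectrum(ma, law)`: above-threshold peak counts drawn from a
  linear law (default slope 10, intercept 0, chosen so MA 5–25 maps to
  a plausible 50–250 peaks; configuration, not an instrument claim),
  plus decoy peaks placed at 0.1× the default filter threshold so they
  are filtered out by construction.
* `make_run(profile, law)`: full MS1+MS2 mixture runs whose precursor
  schedule comes from `dda_select()` itself.

Passing tests on these inputs demonstrate that the machinery is
self-consistent: the estimator recovers the generating law (median
slope within 5% at n = 500; ~90% band coverage), the DDA logic selects
and excludes as specified, and a mixture seeded with one high-MA ion is
flagged while an all-low mixture is not. They do not demonstrate
instrument realism: real fragmentation chemistry, isotope envelopes,
adducts, co-isolation and matrix effects are all absent from the
generator, and the synthetic peaks-vs-MA law is cleaner than the
empirical correlation (reported at r ≈ 0.89 on real standards).
Calibration against real spectra requires real standards.

## Problem sizes and limitations

The shipped tests run the oracle comparison on ~200 random molecules of
up to 8 bonds, chance curves on 10^3 trees to depth 30, and calibration
on 300–500 standards — sizes chosen so the whole suite completes in a
few minutes on one CPU while leaving every claim it makes fully
exercised. Known limitations: the split-branch value is an upper bound,
not the exact index (the suite observes occasional +1 gaps on small
graphs); the greedy regime's fragment-size cap can loosen the bound on
large, highly repetitive molecules; `exact_ma()` is limited to 8 bonds;
V3000 connection tables and stereochemistry-aware assembly are
unsupported; and the chance model is agnostic by design — it says
nothing about any particular reaction network, only about the size and
accessibility of chemical space.
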