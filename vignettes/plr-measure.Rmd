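---
title: "The path-label reconciliation dissimilarity: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The path-label reconciliation dissimilarity: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plrdist)
```

## The objects and the model

A reconciled gene tree is a tuple (G, S, μ, l): a rooted gene tree G whose
internal nodes have at least two children, a rooted *binary* species tree
S, a total map μ from gene nodes to species nodes, and an event labeling l
with leaves `extant` and internal nodes `dup` or `spec`. Three rules make a
reconciliation valid, and `validate_reconciliation()` audits each
separately rather than throwing: leaves map to extant species; μ is
time-consistent along every edge; and a speciation has exactly two
children whose species lie under distinct children of its own species.
Non-binary species trees are rejected at parse time — the theory below
(speciation separation, the diameter argument) assumes binarity, and
silently resolving polytomies would manufacture information.

The dissimilarity between comparable reconciliations matches each node v of
one tree to m(v), the lowest node of the other tree covering v's clade,
then adds a *path* penalty (species-tree distance between μ₁(v) and
μ₂(m(v))) and a *label* penalty (1 if the event labels differ), weighted α
and 1 − α. Both directions are summed. The components are exact integers;
only the α-weighting introduces floating point, and results report the
integer components separately so exact tests never touch reals.

Two properties shape the implementation:

* **Linear-time computation.** m is built in one postorder pass, folding
  children's images through lca queries of the target tree; the number of
  queries is strictly below the edge count of the source tree (asserted in
  the tests via a query counter). Distances use
  `depth(u) + depth(v) − 2·depth(lca)`. The lca index is an Euler tour
  with a sparse table — O(n log n) preprocessing and O(1) queries. The
  strictly linear preprocessing known in the literature would gain nothing
  at the problem sizes this package targets, so the simpler structure is
  used deliberately.
* **Semi-metric under LDR-equivalence.** d_plr is zero on pairs whose
  *least duplication-resolved* forms are isomorphic: disagreements confined
  to chains of same-species duplications are invisible, by design — those
  branchings carry no signal. `least_duplication_resolved()` contracts
  redundant edges by repeated scans to a fixpoint; contraction is
  order-independent (tested by contracting in opposed orders), and the
  parent keeps its identity when an edge collapses. Isomorphism is decided
  by canonical bottom-up clade hashing, valid because the shared, uniquely
  named leaves force the bijection — no general graph-isomorphism machinery
  is needed. The triangle inequality genuinely fails on non-binary trees:
  `fig3_fixture(k)` reproduces a three-tree construction whose pairwise
  values are closed forms in α and k, and the tests check all six directed
  formulas on a grid.

## Tunable parameters

* `alpha` (default 0.5, unitless, in [0, 1]): weight of the path component
  against the label component. 0.5 treats them equally. Because d_path can
  grow with the product of gene count and species count while d_lbl is
  linear in gene count, the symbolic form `alpha = "1/n"` (one over the
  number of species) is accepted everywhere and resolved at call time; it
  keeps the two components on comparable scales for large species trees.
* `decay_rate` (default 0.7, per species-tree edge): the simulator picks
  the pair of lineages to merge with probability proportional to
  exp(−decay_rate · d), d the species distance between their current
  species. The default is the rate used for the distance-distribution
  experiments this generator emulates; smaller values drive ancestral
  nodes toward the species root and inflate duplications.
* `spec_probability` (default 0.5): when the lca rule permits a speciation
  (the merged node's species differs from both children's), the label is
  drawn as `spec` with this probability. The source description leaves the
  choice free, so it is exposed as a parameter with an even default.
* Seeds: every stochastic entry point (`random_species_tree()`,
  `random_gene_set()`, `simulation_config()`) takes an explicit seed;
  identical configurations reproduce identical trees.

## What the simulator does and does not emulate

`simulate_reconciliation()` builds scenarios bottom-up on a *fixed* gene
set, which is exactly what pairwise comparison needs: all outputs over the
same gene set are comparable by construction, and every output is a valid
reconciliation using the lca-mapping (the central contract, audited over
hundreds of draws in the tests). It does not model losses, transfers,
branch lengths or sequence evolution, and its species-tree generator is
uniform sequential leaf attachment — shape diversity, not a realistic
macroevolutionary model. Passing tests therefore demonstrate correctness
of the measure and its theory on the stated model class, not calibration
against real gene families; inferred trees from real data additionally
carry estimation error that no simulation here mimics.

## Normalization and diameters

For a fixed species tree and one gene per species, the exact diameter is
2α·H(S) + (1 − α)(2n − 2), with H(S) the sum of root-to-internal-node
distances (at most (n−1)(n−2)/2, with equality exactly for caterpillars).
`extremal_pair()` constructs a pair attaining it, used as a self-check.
`plr_normalize()` refuses theoretical normalization outside the
one-gene-per-species regime instead of extrapolating — the formula is
proved only there; the empirical-max mode divides by the largest value
observed in a pool and is regime-free. Upper bounds 3n − 8 and 2n − 5 for
the ELRF/LRF diameters are exposed as constants for side-by-side
normalization; those distances themselves are out of scope, and the bounds
are treated strictly as upper bounds, not as attained diameters.

## Rooting evaluation

`best_rootings()` subdivides every edge of an unrooted gene tree, roots
there, lca-reconciles the candidate (μ from the lca-mapping, labels from
the lca rule) and scores it against a reference reconciliation. Ties are
never broken: the size of the Best set is itself the measurement of
discriminatory power. The self-recovery guarantee — the true rooting scores
exactly 0 and sits in the Best set — holds when the reference is the
lca-reconciliation of the true rooted topology, which is how the package's
experiments define the gold standard; a reference with hand-set labels
that deviate from the lca rule need not be recoverable at distance zero.

## Numerical and degenerate-input choices

* Distances are edge counts; branch lengths in input Newick are parsed and
  discarded. depth(root) = 0.
* Child order is preserved from input but never semantic; all operations
  are invariant under reordering (tested).
* Unnamed internal nodes receive deterministic preorder-indexed names at
  parse time, so node identity is stable across round-trips through the
  NHX dialect (`S=` species, `Ev=` event; a `node/species/event` table is
  accepted as an alternate).
* Single-leaf gene trees are valid reconciliations and are at distance 0
  from themselves; incomparability is a result state (`comparable = FALSE`,
  value `Inf`), not an exception, so pairwise matrices stay numeric.
* Comparability condition (3) — equal leaf species — can be relaxed
  (`require_leaf_species_equal = FALSE`), in which case leaves contribute
  to the path component; the semi-metric theory is stated for the strict
  setting.

## Problem sizes used by the test-suite replications

The packaged experiments run at desk scale, chosen so the whole suite
completes in well under a minute while still exercising every property:
diameter attainment on 100 random species trees of up to 50 leaves across
five α values; distance distributions over 50 simulated reconciliations on
10 species (≤ 5 genes per species, 1225 pairwise values, all finite) and a
separate one-gene-per-species pool of the same size whose
theoretically-normalized values all fall inside [0, 1) — the diameter is
hard to reach in practice; semi-metric properties over 500 simulated pairs
on 6 species; m-map-versus-brute-force checks up to ~100-leaf gene trees;
and 100 rooting self-recovery scenarios on 10 species.

## Known limitations

Transfers (and transfer-aware time consistency), branch-length-weighted
path components, diameters outside the one-gene-per-species regime, and
distances between trees with different leaf sets are all out of scope.
Whether binary gene trees can violate the triangle inequality remains
open, as does tightness of the ELRF/LRF diameter bounds.
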