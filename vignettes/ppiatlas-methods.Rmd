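---
title: "Methods: multi-faceted decomposition of annotated PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-faceted decomposition of annotated PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiatlas)
```

## The problem

A protein–protein interaction (PPI) network usually admits several valid
functional organizations at once: by complexes, by pathways, by regulatory
machinery. Single-view graph clustering collapses these onto whichever
organization its objective favors. `ppiatlas` instead produces an *atlas* of
`n` *facets* — alternative decompositions of the same network into possibly
overlapping modules — that are kept mutually orthogonal, structurally (little
edge sharing between the modules of different facets) and functionally (the
GO terms behind different facets are far apart in the ontology DAG).

The decomposition is driven entirely by two inputs besides the network: the
GO DAG and protein-to-term annotations. Annotations are propagated upward
(true-path rule): a term is flagged for a protein iff the term or one of its
descendants is directly annotated to it. Every GO term `t` then generates
*candidate subnetworks*: the connected components of the subgraph induced by
the proteins flagged for `t`. The atlas couples a partition of the
assignable terms into disjoint *function bundles* `B_1..B_n` with a facet per
bundle, each facet selecting its modules only from candidates whose
generating term lies in its bundle. This restriction makes every module
*functionally bounded* by its bundle — each member carries at least one
bundle term, with the bound threshold fixed at 1 by default (configurable for
seeds coming from initializers that do not guarantee term sharing).

## Distances and scores

Four quantities drive the optimization. All live in one function each, so a
variant can be swapped without touching the engine.

* **Functional distance** between terms: the minimum over common ancestors
  `r` of `len(t1→r) + len(t2→r)`, where `len` is the shortest directed hop
  count in the DAG. We treat the ancestor relation as reflexive, so a parent
  and child are at distance 1 and `d(t, t) = 0`. The distance is symmetric;
  the triangle inequality is not implied and not assumed. Information-content
  measures (Resnik, Lin) are deliberately out of scope: hop counts keep the
  distance integer-valued and parameter-free.
* **Structural distance** between subnetworks: the edge Jaccard distance
  `1 − |E1 ∩ E2| / |E1 ∪ E2|`. It is symmetric, bounded in [0, 1], 0 exactly
  on identical edge sets and 1 on edge-disjoint ones. A min-normalized
  overlap (`1 − |E1 ∩ E2| / min(|E1|, |E2|)`) is available behind
  `struct_method = "min_overlap"` for users who want containment to count as
  identity. Degenerate case: two edgeless subnetworks are at distance 0 if
  their node sets coincide and 1 otherwise; an edgeless versus a non-empty
  edge set gives 1.
* **Specificity** of a term for a cluster: `|C|` over the number of network
  proteins flagged with the term. It down-weights generic terms — a
  5-protein cluster sharing a term carried by 1000 network proteins scores
  0.005 — and reaches 1 when the cluster exhausts the term's carriers.
* **Combined distance**: `alpha · d_func + (1 − alpha) · d_struct`,
  everywhere a functional and a structural signal must be merged (centroid
  assignment, inter-facet orthogonality).

## The alternating optimization

The joint objective weighs mean pairwise inter-facet orthogonality
(`lambda`) against total intra-facet modularity, the sum over selected
modules of `density × specificity` (`1 − lambda`). Maximizing it exactly is
intractable (dense-subgraph objectives are NP-hard), so the engine is an
alternating local search:

1. **Initialization.** The default initializer ranks candidates by
   `density × specificity` and greedily keeps the best `|V|/20` whose
   pairwise structural distance stays ≥ 0.5, then assigns them uniformly at
   random (from `seed`) to the `n` facets. Each facet's bundle is seeded with
   its modules' generating terms; a term claimed by several facets goes to
   the one holding its largest module. The initializer is pluggable
   (`facets_config(initializer = ...)`) because the start point legitimately
   shapes the output of any hill climber; any function returning candidate
   indices can stand in.
2. **Step 1 — update the partition.** Every candidate is assigned to the
   facet with the smallest *mean* combined distance to the facet's current
   modules (empty facets are infinitely far). Each term is then reassigned by
   majority vote over its candidates. The per-iteration count of terms that
   switch bundles — the *functional reassignment* — is the convergence
   statistic.
3. **Step 2 — update the atlas.** Facets are rebuilt from scratch by greedy
   profit maximization. Every vertex carries an information budget of 1 per
   facet. A candidate's revenue is `density × specificity × (sum of its
   members' remaining budgets in that facet)`; its cost is `gamma` times the
   maximum edge-overlap similarity (`1 − d_struct`) to modules already
   selected in *other* facets. Facets pick in index order, one strictly
   profitable candidate per round; a selection zeroes the facet's budgets on
   the module's vertices, so a vertex funds at most one selected module per
   facet and exact re-selection is impossible. Rounds repeat until no facet
   can pick.

The loop stops when the reassignment count falls below `theta` or after
`max_iter` iterations (a non-convergent run is returned with
`converged = FALSE`). When Step 1 reaches a fixed point the whole state is
stationary: Step 2 is deterministic given the partition, so the test suite
asserts that one extra alternation changes nothing.

### Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n` | 2 | number of facets; choose by how many organizations you expect to read |
| `alpha` | 0.091 | weight of hop distance vs edge Jaccard; set so a typical ~10-hop functional scale and the [0, 1] structural scale contribute at the same order of magnitude |
| `lambda` | 0.5 | orthogonality vs modularity in the reported objective; the alternating heuristic itself does not consume it, so it only affects the trace and summaries |
| `theta` | 0.01 | convergence threshold; values < 1 are a fraction of the assignable term set (1% by default), values ≥ 1 an absolute term count |
| `gamma` | 1 | penalty weight; with unit budgets it puts the cost of duplicating a module on the scale of one unit-density vertex of revenue |
| `min_size` | 3 | modules below this size are dropped, both at candidate generation and in the output — three proteins is the conventional floor for a meaningful module |
| `max_iter` | 30 | safety stop; desk-scale runs converge in well under ten iterations |
| `seed` | 1 | drives the single source of randomness (initial assignment) |

Budgets start at 1 and are zeroed on selection; these constants are a design
choice (the profit model only needs revenue and cost to share a scale), and
`gamma` is exposed for users who want stronger inter-facet repulsion.

### Tie-breaking and degenerate inputs

All ties are broken deterministically so that equal inputs and seeds give
bit-identical atlases: the candidate pool is sorted by (generating term,
lexicographically smallest member); equal profits and equal centroid
distances resolve to the lowest index; a term whose candidates split evenly
between facets goes to the facet holding the term's largest candidate, then
to the lowest facet index. Terms never carried by any candidate stay
unassigned and are excluded from the reassignment count. A bundle without
candidates simply yields an empty facet (logged, not an error); an
all-empty-facet state is a hard error. Terms with no annotated protein in
the loaded network are excluded from the assignable set outright — they can
never form a candidate.

## What the synthetic generator emulates

`make_planted()` builds the test bed the whole suite runs on: `n_nodes`
proteins carrying two planted views of the same node set. Facet 1 splits the
nodes into `modules_per_facet` contiguous blocks; facet 2 splits them by
index modulo `modules_per_facet`, so every facet-2 module cuts across every
facet-1 module. The two views are orthogonal by construction: within a facet
modules are disjoint, across facets any two modules share only
`~n/m²` nodes, which makes the expected pair-counting Jaccard index between
the planted views analytically small. Each module is directly annotated with
its own leaf of a two-branch ontology (`make_dag`), with branch depth 1, so
same-branch leaves sit at hop distance 2 and cross-branch leaves at 4.
Edges appear with probability `p_in` inside a module (independently per
facet) and `p_out` elsewhere.

The defaults — 300 nodes, 2 branches, 6 modules per facet, `p_in = 0.6`,
`p_out = 0.01` — produce modules of 50 proteins that are connected with
overwhelming probability yet far from cliques, on a network of roughly nine
thousand edges; a full run takes about half a second, so ten-seed experiments
remain cheap. Only 1 or 2 planted facets are supported: the block/modulo
construction defines no third mutually orthogonal partition, and we prefer a
hard configuration error over a silently weaker planting.

What the generator does *not* emulate: scale-free degree distributions, the
size and depth of the real GO (15 synthetic terms versus tens of thousands),
incomplete or biased annotation, and false-positive edges beyond the uniform
background. Passing the recovery tests therefore shows that the machinery is
correct and the optimization behaves as designed on well-posed input — not
that the defaults are tuned for any particular organism's interactome.

## Observed behavior and limitations

Generic terms near the ontology root induce one giant connected component
covering essentially the whole network. Such a candidate has low density but
many members, so under the sum-of-budgets revenue it is often the first pick
of whichever facet owns the root/branch-head terms, after which that facet's
budgets are exhausted and it stays a one-module facet. On the planted
instance this is visible as one facet recovering a planted view exactly while
the other absorbs the generic terms and matches every gold standard only at
the background level. The specificity weight does not suppress these
candidates (a component that exhausts its term's carriers has specificity 1
regardless of how generic the term is); users who want to exclude them can
restrict the ontology (`read_obo(namespace_filter=, subtree_root=)`) or plug
in an initializer that filters by density. This is a property of the profit
model, not a bug in the implementation, and the test suite pins the exact
greedy behavior against an independent profit-recomputation oracle.

Other limitations worth knowing:

* The engine finds a local maximum; different seeds give different atlases.
  The run is bit-reproducible per seed, and the manifest records everything
  needed to rerun it.
* `update_partition` is sticky for terms whose only candidate is itself a
  selected module: the module's zero self-distance dominates the mean at
  small facet sizes. At realistic term counts only a small fraction of
  candidates are selected modules, so the effect fades with scale.
* Pairwise candidate distances are precomputed (`facet_problem`), which is
  quadratic in pool size. This is the right trade at up to a few thousand
  candidates; beyond that the matrices should become lazy.
* "Cellular process sub-domain" of the GO is ambiguous between the
  `biological_process` namespace and the subtree under the term "cellular
  process"; both filters are implemented (`namespace_filter`,
  `subtree_root`) and neither is hard-wired.

## Design choices that were genuinely open

* **Ontology relations:** `is_a` only by default, `part_of` behind a flag —
  the conservative core of GO reasoning.
* **Step 1 centroids** use each module's generating term only. The
  alternative (all terms enriched in the module) would require an enrichment
  model and a cutoff; the generating term is exact by construction.
* **Annotation noise** replaces a direct (protein, term) assignment with a
  uniformly drawn different DAG term, rather than deleting or adding, so
  annotation volume is conserved and re-propagation keeps the table
  ancestor-closed. Replacements are drawn from the full DAG term set: the
  "assignable" set itself depends on the annotations being perturbed, so
  using it as the urn would be circular.
* **Coverage overlap** between facets is the Jaccard of their covered vertex
  sets — symmetric and bounded like the reported ranges.
* **Pair-counting Jaccard for overlapping clusterings** counts a pair as
  co-clustered when the two nodes share at least one module; the index is
  `N11 / (N11 + N10 + N01)` over the union of both coverages, with `0/0 = 0`.
* **The `eval` subcommand** compares written atlases against gold GMT files
  only; the noise operators are library functions (`perturb_edges`,
  `perturb_annotations`) so robustness sweeps stay composable in R rather
  than being frozen into one CLI recipe.

## Problem sizes used by the shipped checks

The unit suite runs on fixtures of 4–120 nodes and ontologies of up to 30
terms, where brute-force oracles (exhaustive common-ancestor search,
union-find components, full pair enumeration, independent greedy
recomputation) are exact and fast. The end-to-end checks use the default
300-node planted instance: ten seeded runs for convergence and recovery
statistics and a 4 × 5 grid (edge-noise ratios 0–0.75, five seeds) for the
robustness trend. The full suite completes in well under a minute on one
CPU.
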