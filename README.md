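# ppiatlas

Multi-faceted functional decomposition of protein–protein interaction (PPI)
networks.

Graph clustering tools return *one* decomposition of a PPI network into
functional modules — usually the protein-complex view that dense-subgraph
objectives favor. Real networks support several equally valid organizations
at once: the same proteins group one way as complexes, another way as
signaling or metabolic pathways, yet another by modification machinery.
`ppiatlas` decomposes a GO-annotated PPI network into an **atlas** of `n`
**facets**: alternative decompositions into (possibly overlapping) functional
modules that are mutually *orthogonal*, both structurally (little edge
sharing between facets' modules) and functionally (the GO terms behind the
facets are far apart in the ontology). It is aimed at systems-biology users
who have an interaction network (edge list or PSI-MI TAB 2.5), the GO DAG
(OBO 1.2) and protein annotations (GAF 2.x or a two-column TSV).

## The model

Let `G = (V, E)` be the network and `D` the GO DAG. Every protein `v` carries
an association vector over the topologically ordered terms of `D`: term `t`
is flagged iff `t` *or one of its descendants* is directly annotated to `v`.
**Candidate subnetworks** are the connected components of the subgraph
induced by the proteins flagged for a term `t` (one generating term per
candidate; candidates of different terms overlap freely). An atlas is a pair
`(A, P)`: `n` facets `F_1..F_n` plus a partition `P = {B_1..B_n}` of the
assignable GO terms into disjoint **function bundles**, with facet `k`
restricted to modules whose generating term lies in `B_k` (so every module is
*functionally bounded* by its bundle: all its members carry a bundle term).

Distances combine with a weight `alpha` (default **0.091**, balancing an
~10-hop functional scale against the [0, 1] structural scale):

- functional distance `d_func(t1, t2)`: minimum over common ancestors `r`
  (reflexive) of `len(t1→r) + len(t2→r)`, hops in the DAG;
- structural distance `d_struct(C1, C2) = 1 − |E1 ∩ E2| / |E1 ∪ E2|`
  (edge Jaccard; 0 on identical edge sets, 1 on edge-disjoint ones);
- specificity `S(C, t) = |C| / |{v ∈ V : t flagged for v}|` — a 5-protein
  cluster sharing a term carried by 1000 network proteins scores 0.005;
- inter-facet orthogonality
  `D_orth(i, j) = alpha · mean d_func(B_i × B_j) + (1 − alpha) · mean
  d_struct(F_i × F_j)`.

The joint objective, maximized heuristically, is

```
J(A, P) = lambda · mean_{i<j} D_orth(i, j)
        + (1 − lambda) · sum_k sum_{M in F_k} density(M) · specificity(M)
```

Optimization alternates, k-means-style, from a seeded random start:

- **Step 1 (update P):** assign every candidate to the facet with the
  smallest mean combined distance to the facet's modules; reassign each term
  to a bundle by majority vote of its candidates. The number of terms that
  switch bundles is the *functional reassignment*; the run converges when it
  drops below `theta` (default 1% of the assignable terms).
- **Step 2 (update A):** rebuild facets greedily under a profit model. Each
  vertex holds an information budget of 1 per facet; a candidate's revenue is
  `density × specificity × (sum of its members' remaining budgets)`, its cost
  is `gamma × max` edge-overlap similarity to modules already selected in
  other facets. Facets take turns picking their best strictly profitable
  candidate; selected members' budgets drop to 0.

## Worked example

The package ships a generator that plants two orthogonal decompositions of
the same 300 proteins (contiguous blocks vs index-modulo classes, each block
and class tied to its own GO leaf) so the whole pipeline runs without
downloads:

```r
library(ppiatlas)

pl <- make_planted(seed = 1)          # 300 nodes, 2 planted facets x 6 modules
at <- run_facets(pl$network, pl$annotations, pl$dag,
                 facets_config(n = 2, seed = 2))
at
#> <facet_atlas> 2 facets (1/6 modules), converged after 4 iteration(s)
#>   objective 2.5941; bundle sizes 9/6; 0 unassigned term(s)

at$trace
#>   iteration reassigned objective
#> 1         1          2  2.580717
#> 2         2          4  1.295781
#> 3         3          4  2.594093
#> 4         4          0  2.594093

bm <- best_match(at, pl$truth_facets)
round(bm$raw, 3)
#>        gold1 gold2
#> facet1 0.164 0.164
#> facet2 0.081 1.000
bm$mapping                            # gold1 -> facet 1, gold2 -> facet 2
bm$injective
#> [1] TRUE
bundle_purity(at$partition, pl$truth_bundles)
#> [1] 0.9285714
```

Reading: the run converged in 4 iterations (reassignment fell below theta).
One facet recovered a planted view exactly (pair-counting Jaccard index 1.0
against its gold standard); the other absorbed the generic root/branch-head
terms, whose induced subgraph is the whole network, and matches both golds
only at the background level (0.164). The mapping from gold standards to
facets is one-to-one, and 92.9% of the assigned branch terms landed in the
bundle matched to their branch.

The same pipeline is scriptable from a shell via the thin wrapper in
`exec/`:

```sh
ppiatlas synth --out-dir demo --seed 1
ppiatlas run --network demo/network.tsv --obo demo/ontology.obo \
  --annotations demo/annotations.tsv --n-facets 2 --seed 2 --out-dir demo/atlas
ppiatlas eval --atlas-dir demo/atlas --gold demo/truth.gmt
```

`run` writes one GMT file per facet, a JSON summary (coverage, pairwise facet
Jaccard index and coverage-overlap matrices) and a manifest with the resolved
configuration, input digests and the per-iteration reassignment trace.

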