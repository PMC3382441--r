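---
title: "Rooting and error-correcting unrooted gene trees under the duplication-loss cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting and error-correcting unrooted gene trees under the duplication-loss cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlrecon)
```

## The problem

Gene families evolve inside species trees, and gene duplication followed by
loss routinely produces gene-tree topologies that disagree with the species
phylogeny even when every inference step is correct. *Reconciliation*
explains the disagreement by embedding a rooted gene tree `G` into a rooted
species tree `S` and charging for the implied events: the classical
lca-mapping `M` sends every gene leaf to the species leaf with its label
and every internal node to the least common ancestor of its children's
images. An internal node `v` with children `w1, w2` is a *duplication* when
`M(w1)` and `M(w2)` are comparable (one ancestral to the other); the
number of lost lineages it implies is `L(M(w1), M(w2))`, where

```
L(a, b) = rho(a, b) - 2 (1 - D(a, b)),
```

`rho` is the path distance in `S` and `D` the comparability indicator.
The *weighted mutation cost* of a reconciliation is
`alpha * duplications + beta * losses` with positive weights
(`alpha = beta = 1` by default, the plain mutation cost).

Two practical complications motivate this package:

1. ML and parsimony programs return **unrooted** gene trees, and the
   reconciliation cost depends strongly on the rooting.
2. Gene trees carry **topological error**, concentrated on poorly
   supported, short (*weak*) edges, and even one misplaced branch can
   inflate the event counts drastically.

`dlrecon` treats both problems at once: it finds the minimum-cost rooting
of an unrooted gene tree in linear time, and searches the neighborhood of
trees reachable by at most `k` nearest-neighbor interchanges (NNIs) —
optionally restricted to weak edges — for the topology and rooting of
minimum cost. On top of this sits a hill-climbing heuristic for the
error-corrected gene-duplication supertree problem: find the rooted species
tree minimizing the total corrected cost of a collection of gene trees.

## Optimal rooting without error correction

Every edge `e` of an unrooted gene tree defines a rooting `G_e` by
subdividing `e` with a new root. The per-edge costs are computed jointly
through a directed labeling of the gene tree: each directed edge `<v, w>`
carries the lca of the species below its source side. Leaf out-edges carry
the leaf's species; internal labels combine by one lca per edge in two
sweeps, so the full labeling costs `O(|G|)` lca queries. LCA queries are
constant-time after an Euler-tour + sparse-table preprocessing of the
species tree (`O(|S| log |S|)` build; the contract is query time, and the
build is a one-off).

Before labeling, the species tree is replaced by its subtree rooted at the
lca of the gene tree's label set (`restrict_species()`). This leaves every
rooting's cost unchanged and guarantees that the root of every rooting maps
to the (restricted) root — written ⊤ — which the star machinery below
assumes.

An (undirected) edge is *symmetric* when zero or two of its directed labels
equal ⊤, *asymmetric* when exactly one does. Each internal node with its
three incident edges forms a *star*, classified S1–S5 by the placement of ⊤
among its three outgoing and three incoming labels: S1 = (2 outgoing, 1
incoming), S2 = (2, 0), S3 = (3, 1), S4 = (3, 3), S5 = (3, 2). These five
types are exhaustive for labelings arising from actual gene trees; the
classifier (`star_types()`) fails loudly on anything else rather than
guessing, since an unclassifiable star can only mean an inconsistent
labeling. Two properties tie the star types to the optimal-edge set
`Min_G` (all edges whose rooting attains the minimal cost): when
`|Min_G| > 1` it is exactly the union of the edges of S4/S5 stars, and when
`|Min_G| = 1` its element is a symmetric edge inside an S2 or S3 star; at
most two S2 stars can occur and then they share an edge. The per-edge costs
themselves are computed in one pass: each internal node contributes a
closed-form term depending only on which of its three edges points toward
the root, so moving the root across one edge updates the total in O(1), and
a single tree traversal yields every `sigma_e`.

`unrooted_reconcile()` returns the cost vector, `Min_G`, a canonical
representative (deterministically chosen as the optimal edge with the
lexicographically smallest leaf-label split) and the event counts of its
rooting. `brute_force_optimal()` does the same by rooting every edge and
reconciling from scratch; it shares no code with the labeling path and is
kept deliberately naive as the test oracle.

## Constant-time NNI updates

The correction search needs the optimal cost of *many* neighboring
topologies, so recomputing the labeling per neighbor would be wasteful. An
NNI across an internal (center) edge only changes the two directed labels
of the center edge itself: the labels on the four side edges describe the
four hanging subtrees and their complements, and neither changes when two
subtrees swap sides. `apply_nni()` therefore updates the labeling with two
lca queries.

The optimal-edge set is maintained by a nine-way case analysis on how
`Min_G` meets the five frame edges (center plus four sides), distinguishing
whether the intersection is empty, the center alone, a single side edge, a
full side star, or all five edges, refined by the symmetry of the involved
edges before and after the operation. The cost is updated by closed-form
differences evaluated at an optimal edge that survives the operation (one
always does): when the center survives, the difference is a four-argument
form `delta4(a1, a2, a3, a4)` of the subtree mappings; otherwise a
three-argument form `delta3` indexed by which subtree retains an optimal
edge. When the surviving subtree is not identified by the intersection
itself (the empty-intersection case), it is found in O(1) by following the
unique non-⊤ outgoing label away from the center, which is well defined
because both center stars are then of type S1.

Two choices in the case analysis were genuinely open and were fixed by
validating against the brute-force oracle on randomized NNI walks:

* when a single non-center optimal edge `e_i` sits in the frame and the
  center becomes symmetric, the replacement star is the one spanned by the
  transformed center and the transformed `e_i` (not some other side edge);
* the three-edge intersection case requires the two side edges to lie on
  the same side of the center (they must form a star with it), and when
  exactly one of them is asymmetric it plays the role of the discarded
  edge.

If the case analysis ever meets a configuration outside its taxonomy, the
state is recomputed from scratch and the event counted in `n_fallback`;
the test suite requires zero fallbacks over 100 random fixtures x 50-step
walks, so the fallback is a tripwire, not a crutch. Undo tokens restore
the exact previous state, which is what makes the depth-first search below
allocation-free.

## The k-NNI correction search

`correct_gene_tree(G, S, k, omega)` minimizes the rooting cost over all
trees reachable by at most `k` NNIs whose center edge is *eligible*:
every internal edge by default, or the internal edges of the input tree
with length strictly below `omega` (weak edges) in the restricted variant.
Neighborhood semantics are sequences of up to `k` operations applied
successively, with edges reusable across steps; edge identity (and hence
eligibility and length) persists through rewiring because an NNI only
moves edge endpoints, never creates or destroys edges. The search is a DFS
over NNI sequences on one mutable state with constant-time cost updates
and undo; its cost is `O(l^k)` for `l` eligible edges, plus the linear
setup. Duplicate topologies in the enumeration are revisited rather than
deduplicated (they only cost time at these scales); an optional
canonical-form memo (`dedup = TRUE`) is available for larger `k`.

Ties among equally optimal corrections go to the shorter NNI sequence and
then to the lexicographically smallest canonical topology, so reports are
deterministic. A tree "has errors" when some NNI variant beats the
uncorrected optimum strictly. `knnic_total()` sums corrected costs over a
family collection; `filter_by_mu()` rejects trees with more than `mu` weak
edges, the screening step used before supertree inference. `omega = 0`
marks nothing weak (the comparison is strict), and an edge without a
length is never weak: silently treating missing lengths as zero would mark
every edge weak, which is the opposite of the intended conservatism.

## Supertree search

`hill_climb()` minimizes `total_cost_of_tree()` over rooted species trees.
The local move set is all rooted NNIs plus all rerootings of the current
candidate: the duplication objective depends on the species root, so
rerooting moves are necessary for the search to distinguish rootings;
adding them keeps the move set minimal while complete in that respect.
Starts are uniform random rooted topologies (sequential leaf addition with
uniform attachment, which is exactly uniform over rooted labeled
topologies); descent is steepest and strict — sideways moves are
disallowed so every trajectory terminates — and 20 restarts (the default)
mitigate local optima. All distinct final trees are ranked by cost and all
co-optimal trees reported. Candidate evaluations are memoized on the
canonical rooted topology, which roughly halves the work because
consecutive neighborhoods overlap. The exact complexity of the underlying
optimization problem is unknown (related supertree problems under the
duplication model are NP-hard), which is why a heuristic is offered at
all.

## The simulator, and what it does and does not show

`random_species_tree()` draws uniform rooted topologies with unit branch
lengths; `evolve_gene_tree()` runs a constant-rate birth-death process
down the species tree (defaults `dup_rate = loss_rate = 0.15` events per
lineage per unit length), labels surviving lineages by their species and
suppresses loss-induced unary nodes. Families with fewer than `min_leaves`
(default 4, the smallest size with an internal edge) are resampled. The
default rates give a mean of roughly one to two events per family, matching
the premise that gene trees are mostly correct with small error.

Gene-tree branch lengths are decorative for reconciliation but essential
for the weak-edge machinery, so they are generated with a crisp two-regime
structure: a log-normal body (`meanlog = -0.7`, `sdlog = 0.6`; median about
0.5, little mass below 0.1) and a short regime (uniform on [0.01, 0.05])
assigned to a configurable fraction (default 0.3) of internal edges. An
`omega` of 0.1 separates the regimes exactly, so threshold choice is not
confounded with recovery in the validation experiments.
`inject_errors()` applies random NNIs centered on short internal edges
only, recording the moves so reachability is checkable.

The simulator reproduces the *statistical shape* the correction method
assumes — duplication-loss families, error localized on short edges — and
nothing more. It does not model sequence-level inference, alignment noise,
rate variation among lineages, transfer, or deep coalescence; passing
recovery tests on it shows the algorithmic machinery is exact and that the
weak-edge heuristic works when its premise holds, not that the premise
holds for any particular empirical data set.

## Numerical choices and degenerate inputs

* Costs are accumulated as doubles; ties and equalities are compared at
  tolerance 1e-9. With integer event counts and binary-representable
  weights the arithmetic is exact, and the incremental updates are checked
  bit-for-bit against recomputation in the tests.
* Two-leaf gene trees violate the machinery's at-least-one-internal-node
  assumption; their single rooting is evaluated directly and the star
  machinery bypassed.
* Families whose leaves all carry one species collapse the restricted
  species tree to a single leaf; every rooting then costs
  `alpha * (internal nodes + 1)` and every edge is optimal, handled as an
  explicit degenerate path.
* Gene trees whose label set is a strict subset of the species set are
  reconciled against the restricted subtree (no contraction of the gene
  tree), which provably leaves costs unchanged.
* Newick I/O accepts both rooted-binary and trifurcating conventions for
  unrooted trees (ML tools emit both); canonical output uses a
  trifurcation anchored at the internal neighbor of the smallest-labeled
  leaf. A degree-2 root is suppressed with its two incident lengths merged
  additively.

## Validation sizes

The shipped test suite validates, among others: the loss-count identity
and the contribution definitions on 200 random trees each; exact
agreement of the linear-time rooting with the root-every-edge brute force
on 500 random instances (up to 16 species, 24 gene leaves, three weight
settings); exactness of the incremental NNI maintenance along 100 x 50
random walks with zero fallbacks; correction-search equality with
materialized neighborhoods for k <= 2; recovery of a single injected NNI
in 100 replicates (equality in at least 95); and species-tree recovery on
8-taxon, 30-tree simulations with 20-run hill climbs in 3 replicates.
These sizes were chosen as the smallest that exercise every code path of
the case analysis while keeping the whole suite comfortably runnable on a
laptop; the properties themselves are size-free.

## Known limitations

* Only duplication and loss are modeled; transfer and deep coalescence are
  out of scope, as are duplication-episode clustering and drawing of
  embeddings.
* The correction neighborhood grows as `l^k`; `k` beyond 3 on trees with
  many weak edges is feasible only with the memoized variant and patience.
* The hill climber offers no optimality guarantee and no clade support
  values; co-optimal output and restarts are the honesty mechanism.
* Non-binary species trees and partially labeled gene leaves are rejected,
  not resolved.
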