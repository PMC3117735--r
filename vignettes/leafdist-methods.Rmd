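---
title: "Methods: edit distances for leaf-labelled trees on free leafsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edit distances for leaf-labelled trees on free leafsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafdist)
```

## The data model

`leafdist` works with unrooted trees whose leaves carry unique labels and
whose internal nodes are anonymous. Such a tree is fully determined by its
leafset together with the set of *non-trivial splits* — the bipartitions
induced by deleting each internal edge. We store exactly that: trivial
splits (one leaf versus the rest) are implied by the leafset and never
materialised. This convention is what makes operation counting unambiguous:
the Robinson–Foulds distance, forced-contraction counts, and contraction
scripts all refer to non-trivial splits only, while subsplit support
(below) deliberately re-admits the implied trivial splits as candidate
supersplits.

Two invariants are enforced at construction: all stored splits live on the
tree's leafset and are pairwise compatible (at least one of the four
pairwise side intersections is empty — the classical condition under which
a split set is realisable as a tree). Trees with up to three leaves have no
non-trivial splits; every distance between same-leafset trees that small is
zero, and the code treats this as an ordinary case, not an error.

## Editing operations

*Contraction* deletes one internal edge, i.e. removes one non-trivial split;
only non-trivial splits may be contracted, since contracting a pendant edge
would delete a leaf. *Pruning* removes a leaf and suppresses the resulting
degree-2 node. On the splitset, pruning strikes the leaf from every split
and then discards splits that emptied a side, became trivial, or collapsed
into duplicates of surviving splits. Each non-trivial split lost this way is
a *forced contraction*. `prune()` returns the count plus the post-pruning
names of the lost splits, because recovered edit scripts cite them in that
restricted form.

The order of operations within a script never changes the resulting tree:
contractions and prunings act on disjoint carriers (edges versus leaves),
and set removals commute. `apply_script()` exploits this, matching a
contraction target named on a smaller leafset against the unique current
split whose restriction equals it; when a forced contraction has already
been realised implicitly by an earlier pruning, the explicit entry is
consumed as a no-op. Where a pruning makes two edges' split representations
collide, either edge may be named — the duplicates are interchangeable, and
we contract the lexicographically smallest key for determinism.

## The edit distance

Given positive costs `cost_c` (contraction) and `cost_p` (pruning), the edit
distance is the minimal total cost of a pair of per-tree scripts reaching a
common tree, with forced contractions charged at `cost_c`. With that
accounting the distance is a metric (identity, symmetry and the triangle
inequality are exercised over seeded random triples in the test suite). The
*NFC* variant sets the forced-contraction charge to zero; it is exposed as a
dissimilarity — nothing in the package assumes metric axioms for it.

The exact search uses two structural facts: operation order is irrelevant,
so prunings can be explored before contractions; and no optimal script
contracts a split present in both trees, so the contraction-only cost of a
state is just `cost_c` times the R-F distance. Phase 1 prunes the leafset
symmetric difference from the respective trees (these leaves can never
survive). Phase 2, on a common leafset, takes the minimum of the
contraction-only base case and, for each common leaf, pruning it *from both
trees* (a leaf present in both cannot leave only one and still unify) and
recursing. States are memoized on the set of remaining leaves — order
irrelevance is exactly what licenses that key — giving at most `2^n` states.
Internally the search runs on integer bitmasks with a table-driven
popcount; the public split objects are only rebuilt for script recovery.

Numerical choices: costs are compared with an absolute tolerance of `1e-9`,
so real-valued costs are safe; integer costs are exact. Ties are broken
toward the contraction-only base case first and then the lexicographically
smallest pruned leaf. The *distance* is tie-free; the *script* is one
optimum among possibly many, and the documentation says so rather than
pretending uniqueness.

The brute-force oracle used in testing is a flat enumeration over kept
leafsets with a closed-form cost (prunings + forced contractions + residual
R-F), kept deliberately separate from the recursion it checks. The
recursion's assumption that Phase-1 prunings can be committed before any
Phase-2 contraction is itself covered by that oracle on trees of up to
seven leaves.

## Reference measures

`rf_dist()` is the symmetric-difference count over non-trivial splits,
defined only on a shared leafset. `mast()` finds a maximum agreement
subtree by memoized top-down leaf removal over subsets of the common
leafset; on free leafsets the distance counts each removed leaf of the
union once. This once-counting is the variant that matches the worked
values this package reproduces; a twice-if-removed-from-both variant exists
conceptually but is not implemented. Among equally large agreement leafsets
the lexicographically smallest is reported. `p_distance()` restricts the
script space to prunings (plus their forced contractions) and minimises
cost over agreement leafsets; `c_distance()` restricts it to contractions
and is therefore `cost_c` × R-F. Both exist mainly as the two degenerate
corners between which the edit distance interpolates. All exact searches
are exponential by design — polynomial MAST algorithms from the literature
are out of scope — and practical to roughly 17 leaves.

One accounting subtlety is worth recording. Pruning-only unification
charges `cost_p` per leaf *per tree* (a leaf removed from both trees costs
`2 * cost_p`) plus the forced contractions in each tree. This reproduces
the package's reference values for the 8-leaf pair (p-distance 12 at
pruning cost 2, forced contractions at 1) and is consistent with the
documented edit-distance recursion; a reader comparing against older
summary tables of such examples may find one entry that assumed a cheaper
accounting for a 5-leaf pair — we treat the consistent per-tree rule as
normative.

## Consensus

`consensus_strict()` and `consensus_majority()` are split-frequency
constructions on a shared leafset (majority means strictly more than half;
such splits are automatically pairwise compatible). `tree_edit_consensus()`
generalises the pairwise search to a profile: a pruning, when chosen, must
remove the leaf from *every* tree (`n * cost_p` plus forced contractions);
the base case contracts each tree down to the strict consensus of the
current restricted profile. For two trees the score provably coincides with
the edit distance, which the tests assert; with prohibitive pruning cost on
a shared leafset the result collapses to the strict consensus. The
definition optimised is "minimal-cost script": where an informal account
of such a consensus names the tree reached after more aggressive pruning,
the minimal-cost tree is returned instead — users wanting a leafier
consensus should raise `cost_c` relative to `cost_p`, which is precisely
what the cost model is for. The consensus tree is not unique in general;
ties break exactly as in the pairwise search, and no enumeration of
co-optimal trees is offered.

## Frequent subsplits

A split `s` is *supported* by a tree when it is a subsplit of at least one
of its splits, the implied trivial splits included; support in a profile
counts supporting *trees*, not splits, so structure repeated many times
inside a single tree does not inflate support. `representative_splitset()`
returns the maximal frequent subsplits at a minimal support `minsup`
(`1` = strict, `0.5` = majority; values above 1 are absolute tree counts —
the scalar `1` is read as 100%, not one tree).

No mining algorithm is inherited here, so the package defines one:
candidates are closed under *pairwise maximal common restriction* — for
splits `A|B` and `C|D`, the only maximal common subsplit candidates are
`(A∩C)|(B∩D)` and `(A∩D)|(B∩C)` — folded left-to-right across the profile
for the unanimous case, and unioned over all qualifying tree subsets before
re-maximalising for general `minsup`. Subsplit support is anti-monotone
(any subsplit of a frequent split is frequent), which is why no maximal
frequent subsplit can escape the closure; correctness is nevertheless
anchored to a brute-force oracle that enumerates every restriction of every
observed split on small profiles. The subset-union step is exponential in
the profile size and intended for the desk scales this package targets.

For `minsup > 50%` any two members restricted to a common leafset are
compatible, so the splitset can be visualised as trees:
`splitset_to_trees()` builds one tree per distinct member leafset plus one
on the intersection of those leafsets, asserts that every member reappears
restricted in at least one output tree, and — for same-leafset profiles —
that the intersection tree refines the strict consensus.

`fs_dissimilarity()` is `1 − |SFS(T1,T2)| / |S1 ⊎ S2|`, where both counts
include trivial splits and the modified union `⊎` keeps only the supersplit
of any sub/supersplit pair. Including trivial splits is not cosmetic: the
worked 9-leaf example in the test suite (value 0.6 = 1 − 12/30) requires
it. The measure is symmetric, lies in `[0, 1]`, and is zero exactly for
identical splitsets, but it is not a metric and is never treated as one.

## The simulation harness

`random_tree()` draws binary trees uniformly over labelled unrooted binary
topologies by sequential uniform edge attachment (each new leaf subdivides
a uniformly chosen edge of the current tree); a property test checks the 15
five-leaf topologies for uniformity over 10,000 draws. "Unconstrained"
trees contract each internal edge of a binary draw independently with
probability `contraction_prob`; the default 0.25 was chosen once as a
moderate polytomy rate — enough multifurcation to distinguish the models
without collapsing most trees toward stars — and is exposed as a parameter
rather than revisited. Under `free_leafset` the leaf count is uniform on
`4:n_leaves` with labels sampled from a universe, emulating profiles whose
trees cover different taxon subsets.

Mutations are the three elementary changes the distances respond to:
removing a random split, pruning a random leaf, and the *nearest
non-brother interchange* (NNBI) — swapping the labels of a uniformly chosen
pair of non-sibling leaves at minimal topological distance, which preserves
the leafset and can be levelled by one contraction or one pruning per tree
when the swapped cousins are three edges apart. Leaf-to-leaf topological
distances are taken from cophenetic distances on unit branch lengths via
ape.

Two harnesses drive them. `distance_distribution()` evaluates a set of
measures on one shared stream of random pairs — the fair way to compare
discriminative power — and `distance_dynamics()` tracks mean distance
against the number of mutations. Conventions on awkward pairs are explicit
rather than silent: R-F on different leafsets records the maximum possible
value `|S1| + |S2|` (so its free-leafset "distribution" mostly reflects the
chance of drawing equal leafsets, and it *decreases* with pruning
mutations); measures genuinely undefined on a pair (empty common leafset,
possible when two 4-leaf trees are drawn from an 8-label universe) record
`NA` and are dropped from summaries. Two exact linearities are asserted per
run rather than on average: unit-cost edit distance equals `k` under `k`
contraction mutations, and the MAST distance equals `k` under `k` prunings.

What the generator does *not* emulate: branch lengths, taxon-sampling bias,
correlated topologies within a profile, or trees beyond ~20 leaves (the
exact searches are exponential). Passing tests therefore demonstrate
correctness of the algorithms under the stated random models, not
robustness on empirical gene-tree collections.

## Problem sizes and determinism

The test suite runs the metric axioms on 200 random triples of up to
7 leaves, oracle equivalences on all pairs from an enumerated family of
19 trees of up to 6 leaves, the high-pruning-cost limit on 100 pairs,
mutation linearity on 100 seeded 8-leaf trees, and discriminativeness on
1000 seeded 8-leaf pairs — sizes chosen so the whole suite stays in the
low minutes on one CPU while exercising every search path. All randomness
flows through explicit seeds; identical seeds give byte-identical
experiment tables, which the CLI tests verify end to end.

## Known limitations

* All exact searches (edit distance, MAST, p-distance, tree edit consensus)
  are exponential in the leaf count; 30 labels is a hard cap and ~17 a
  practical one.
* The NFC dissimilarity's metric status is untested territory by
  construction; it is deliberately not used where metric properties matter.
* The frequent-subsplit miner's general-`minsup` path enumerates tree
  subsets and is for small profiles only.
* Newick input discards branch lengths and internal labels by design;
  rooted semantics are not modelled (a degree-2 root is suppressed).
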