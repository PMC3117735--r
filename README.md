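# leafdist

Distance measures and consensus methods for **unrooted leaf-labelled trees on
free leafsets** — trees, such as gene trees from phylogenetic reconstruction,
in which only the terminal nodes carry labels and different trees need not
share the same set of leaves.

Competing evolutionary hypotheses for one gene family often disagree both in
topology *and* in which taxa they cover. The two classical comparison tools
each see only half of that picture: the Robinson–Foulds (R-F) distance counts
split differences but is undefined across leafsets and saturates when a
single "noisy" leaf disrupts every split, while the MAST distance (leaves
removed to reach a maximum agreement subtree) ignores edge-level differences
entirely. `leafdist` implements a **tree edit distance** that closes this
gap, together with the reference measures, consensus constructions and a
simulation harness for comparing them.

## The measure

A tree is encoded by its leafset and its set of non-trivial splits
(bipartitions), one per internal edge. Two editing operations act on it:

* **contraction** — remove one internal edge (one non-trivial split), at cost
  `cost_c`;
* **pruning** — remove one leaf and suppress the resulting degree-2 node, at
  cost `cost_p`. A pruning may force the loss of further non-trivial splits
  (they degenerate to trivial or collapse into duplicates); each such
  **forced contraction** is charged at `cost_c`.

An *edit script* for trees T₁, T₂ is a pair of operation sequences that
transforms both into one common tree; the edit distance

> E(cost_c, cost_p)(T₁, T₂) = min over scripts of Σ operation costs

is a true metric when forced contractions are counted. Setting their cost to
zero gives the NFC dissimilarity, whose response to mutations is nearly
proportional to the number of changes regardless of their type. Both are
computed exactly by a memoized search: prune the leafset difference, then
recursively either contract the split symmetric difference (`cost_c` × R-F)
or prune a common leaf from both trees — exponential in leaves, exact, and
comfortable at desk scale (≤ ~17 leaves).

Also included:

* `rf_dist()`, `mast()`, `p_distance()`, `c_distance()` — reference measures;
* `consensus_strict()`, `consensus_majority()`, `tree_edit_consensus()` —
  consensus trees, the last generalising the edit distance to whole profiles;
* `representative_splitset()`, `splitset_to_trees()`, `fs_dissimilarity()` —
  maximal frequent-subsplit mining across a profile with free leafsets, its
  tree visualisation, and the derived dissimilarity;
* `random_tree()`, `mutate_tree()`, `distance_distribution()`,
  `distance_dynamics()` — seeded random-tree generation (uniform binary or
  multifurcating), contraction/pruning/NNBI mutations, and the two
  experiment harnesses, all returning tidy tibbles with `tidy()`/`glance()`
  and ggplot2 `autoplot()` methods;
* Newick and plain-text split-file I/O (`read_newick()`, `read_split_file()`,
  …) and a command-line interface (`inst/exec/leafdist`).

## A worked example

Two 8-leaf trees that disagree only through the placement of leaf `d`:

```r
library(leafdist)

t1 <- leaf_tree(letters[1:8],
  c("gh|abcdef", "fgh|abcde", "efgh|abcd", "aefgh|bcd", "abefgh|cd"))
t2 <- leaf_tree(letters[1:8],
  c("fg|abcdeh", "dfg|abceh", "dfgh|abce", "defgh|abc", "adefgh|bc"))

rf_dist(t1, t2)        # 10  -- every split differs: R-F saturates
mast(t1, t2)$distance  # 2   -- but the trees agree on 6 of 8 leaves

tree_edit(t1, t2)
#> <tree_edit> distance 6  (cost_c=1, cost_p=1, forced contractions counted)
#> unified tree: {a,b,c,e,f,g,h}: a,b,c,e|f,g,h  a,b,c|e,f,g,h  a,e,f,g,h|b,c
#> subscript T1: p(d), fc(a,b,e,f,g,h|c), c(a,b,c,e,f|g,h)
#> subscript T2: p(d), fc(a,b,c,e,h|f,g), c(a,b,c,e,h|f,g)
```

The minimal script prunes the noisy leaf from both trees (cost 2), absorbs
one forced contraction in each (cost 2), and contracts the two remaining
differing splits (cost 2): distance 6, with the script itself available via
`tidy()`. Raising the pruning cost to 2 makes the same script cost 8;
at pruning cost 3 contraction-only becomes optimal and the distance equals
the R-F value of 10 — the cost model is the tuning knob.

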