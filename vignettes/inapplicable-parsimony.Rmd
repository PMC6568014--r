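---
title: "Scoring morphological characters with inapplicable states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring morphological characters with inapplicable states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inappfitch)
```

## The problem

Morphological character matrices routinely contain hierarchically
dependent characters.  A principal character records the presence or
absence of a structure ("tail: absent (0) / present (1)") and one or more
dependent characters record its attributes ("tail colour: red (0) / blue
(1)").  Under reductive coding, a taxon without a tail is scored `-`
(inapplicable) for tail colour -- the question has no answer there, which
is different from `?` (the tail is there but its colour is unrecorded).

Standard Fitch parsimony offers two treatments of `-`, both flawed.
Treating it as missing data lets ancestral tails change colour in
lineages reconstructed as tailless, so tree length can include logically
impossible transformations.  Treating it as an extra state makes every
loss of the tail drag a pseudo-transformation through each dependent
character, compounding the cost of a single event.

`inappfitch` implements a single-character algorithm that resolves the
applicable/inapplicable dichotomy before counting changes.  The quantity
minimised is a tree *score*,

> score = transformation steps + additional regions of applicability,

where a *region* is a maximal connected part of the tree over which the
character is reconstructed applicable.  Splitting a character into two
regions asserts an independent origin of the structure bearing it, and is
penalised exactly like a transformation.  With no inapplicable tokens the
score reduces to the familiar Fitch length.

## The four passes

Scoring one character on a rooted binary tree uses up to three
traversals; a fourth finalises ancestral state sets.

1. **First downpass.**  Post-order.  Child state sets are combined by
   three rules: if both children carry applicable states and at most one
   carries `-`, the node takes the shared applicable states (or, lacking
   shared ones, all applicable states of both); if both carry `-` and at
   most one carries an applicable state, the node is `{-}`; otherwise the
   union of everything.
2. **First uppass.**  Pre-order.  Each vertex is resolved applicable or
   inapplicable by looking at its three incident branches: it is
   applicable iff at least two of the three directed state sets meeting
   it carry applicable states.  The set entering a vertex from above is
   computed with the same combine rule as the downpass
   (`above(v) = merge(above(parent), sibling's preliminary set)`; for a
   child of the root it is the other child's preliminary set).  This
   "presence over absence" tie-break prefers parallel losses to loss and
   regain.  The root vertex itself is granted a phantom applicable
   ancestor.  Finally, any connected component of applicable-resolved
   vertices that no unambiguously applicable tip adjoins is flipped back
   to inapplicable (see *Numerical choices* below).  Ambiguous tips
   (missing data expanded to "any state, applicable or not") are then
   committed to their parent's resolution.
3. **Second downpass.**  Post-order Fitch restricted to applicable
   states.  Shared child states cost nothing; disjoint applicable child
   sets unite and add one *step*.  A per-node tracker records whether any
   applicable region exists in the subtree; wherever two region-bearing
   subtrees meet across an inapplicable junction, one *region* is added.
   After this pass the score is final.
4. **Second uppass.**  Standard Fitch final-state rules restricted to
   applicable states; a node whose ancestor is inapplicable heads its
   region and keeps its working set.  This pass assigns states only and
   never changes the score.

Characters with fewer than three observed gap-bearing cells are
dispatched to plain Fitch with `-` read as missing: the treatments
provably coincide there, and the cheap path keeps matrix-level scoring
fast.

```{r worked-example}
ex <- two_region_example()
score_character(ex$tree, ex$matrix$columns[[1]])
```

One transformation (1 to 0 inside the first region) plus one additional
region (the independent second patch of state 0) gives a contribution
of 2.

## Design choices where the rules are open

Several points are not settled by the informal description of the
algorithm; the package takes the following positions.

* **Downpass rule order.**  The first rule is read as requiring *both*
  children to carry applicable states; otherwise the rule for the
  one-applicable-child case (which must yield "all applicable and
  inapplicable states") would be unreachable.  When children share
  applicable states the intersection is recorded rather than the union
  of all applicables -- the resolution the score depends on is identical
  either way, and the intersection mirrors Fitch.
* **Directed sets in the first uppass.**  Resolving a vertex against its
  parent's already-resolved flag, rather than against the true directed
  set on the ancestral branch, lets the root's phantom applicability
  reflect a subtree's own applicable content back at it.  The score then
  depends on where the tree is rooted: on the chain tree
  `(t3,(t2,(t4,(t1,t5))))` with states `0` at `t3`/`t5` and `-`
  elsewhere, the flag-based variant scores 0 or 1 depending on the
  rooting.  Message passing with the downpass combine rule gives every
  vertex the same three views whatever the rooting, and restores the
  algorithm's symmetry.  The phantom applicable ancestor is honoured at
  the root vertex only and never propagated into directed sets.
* **Region anchoring.**  With directed sets alone, a vertex surrounded
  by gap-dominated neighbourhoods can be resolved applicable although no
  taxon in its putative region was ever observed applicable.  Such
  "islands" make the reported score disagree with the cost of the
  algorithm's own reconstruction.  An applicable region must contain at
  least one unambiguously applicable tip; components violating this are
  reconstructed inapplicable.  With the repair, on every random instance
  small enough to check exhaustively, some choice of single states from
  the final sets attains exactly the reported score.
* **Dispatch threshold.**  The cheap-path test counts observed cells
  whose state set carries `-` -- the exact `{-}` singletons plus rare
  gap-bearing polymorphisms such as `(0-)`.  Counting singletons alone
  would dispatch a column with two gaps and one `(0-)` to the missing
  treatment and report a score its own reconstruction contradicts.  On
  data without gap polymorphisms (effectively all real matrices) the two
  counts agree.
* **Empty-set fallbacks.**  An applicable node whose preliminary set has
  no applicable part takes its children's applicable union, then the
  applicable part of the set entering from above.  Tie situations in the
  pass rules do not otherwise arise; the combine rule is total and
  nonempty over all pairs of nonempty sets (asserted by a coverage
  test).
* **Weights.**  Steps and regions both cost exactly 1 and are summed
  into a single score; no differential weighting is applied.

The local optimisation is deliberately greedy: the exhaustively
enumerated global minimum of (steps + extra regions) over all single-state
labellings is a lower bound, and can be strictly smaller -- connecting two
patches of applicability through unobserved ancestors may be globally
cheaper than the local rules allow.  The test suite asserts the bound
(and its occasional strictness) rather than equality.

## Baselines, oracle, and search

The two traditional treatments are provided by one Fitch engine
parameterised by token mapping (`fitch_missing_length()`,
`fitch_extra_state_length()`), so the three methods differ only in their
stated treatment of `-`.  `min_cost()` enumerates every labelling of a
small tree and is the package's ground truth; `labeling_cost()` scores a
single labelling (steps between applicable-labelled endpoints, plus
connected applicable components beyond the first).

`ratchet_search()` is a parsimony ratchet: hill climbing under weights
with a random 25% of characters doubled, alternating with climbs under
the original weights, drifting from the current tree and keeping the
best score and every topology on its plateau (canonical unrooted
identities, capped at 10 000 with an overflow flag).  NNI is the default
rearrangement, with SPR available; the perturbation fraction, iteration
count and stopping patience (default: stop once the best score has
survived 250 iterations) are configurable.  On every matrix small enough
to enumerate all topologies, the ratchet's best score matches exhaustive
search under all three methods.  `exhaustive_search()` and the
comparison helpers (`cross_score_table()`, `optimal_overlap()`,
`consensus_overlap()`) implement the three-way protocol of scoring each
method's optimal trees under the others, tallying topologies optimal
under one, two or three methods, and intersecting strict-consensus
bipartitions.

## The synthetic hierarchy generator

`simulate_hierarchy()` emulates exactly the data structure the algorithm
assumes, and nothing more: a principal binary character evolves along a
Yule tree (`simulate_tree()`, unit branch lengths) under a two-state
continuous-time chain with gain and loss rates of 0.3 per unit branch
length; each dependent character evolves under a symmetric chain (total
rate 0.5) along the lineages where the structure is present, draws a
fresh uniform state at each independent gain, and is emitted as `-`
wherever the structure is absent at a tip.  The structure is present at
the root, so vanishing rates yield an invariant, fully applicable
matrix.  Missing tokens are injected uniformly at a configurable rate
(default 0).  Defaults were chosen once as realistic mid-range values --
a handful of expected events per tree -- and are not tuned to any test.

What the generator does *not* emulate: rate heterogeneity across
lineages or characters, correlated dependents, composite coding,
ascertainment ("variable characters only") filtering, or any realistic
model of morphological evolution.  Tests passing on these data show the
coding contract is handled correctly, not that the method is accurate on
real morphology.

## Problem sizes used by the tests

The shipped suite works at desk scale, chosen so the whole run stays in
the order of a couple of minutes: Fitch-equivalence and few-gap
equivalence on 1 000 random trees of 5-20 and 5-15 leaves, rooting
invariance on 100 gap-bearing instances rerooted on every edge,
exhaustive-oracle bounds and reconstruction self-consistency on 50
instances of up to 9 leaves, ratchet-versus-exhaustive equality on three
matrices of 6-7 taxa under all three methods, and 100 generator
replicates checked cell by cell.

## Known limitations

* Characters are unordered; additive (ordered) multistate characters and
  step matrices are out of scope.
* Scoring requires strictly binary rooted trees; polytomies must be
  resolved explicitly (`resolve_polytomies()`).
* At most 30 applicable states per character (32-bit masks).
* The score is locally, not globally, optimal for single characters, and
  characters are scored independently -- the multi-character hierarchy is
  never optimised jointly.
* NEXUS support covers the plain `DATA`/`CHARACTERS` + `MATRIX` layout
  (with `SYMBOLS`, `MISSING`, `GAP`); interleaved matrices are not
  parsed.
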