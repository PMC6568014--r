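# inappfitch

Parsimony analysis of discrete morphological characters that contain
**inapplicable states**.

Reductively coded character hierarchies are ubiquitous in morphology: a
principal character records presence/absence of a structure ("tail:
absent/present") and dependent characters record its attributes ("tail
colour"), scored `-` wherever the structure is absent.  Treating `-` as
missing data lets tree-length calculations count logically impossible
transformations (tail colour changing in a tailless ancestor); treating
it as an extra state compounds the cost of every loss across all
dependent characters.  Both distortions can misdirect tree searches.

`inappfitch` scores a character as

```
tree score = transformation steps + additional regions of applicability
```

where a *region* is a maximal connected part of the tree over which the
character is reconstructed applicable: splitting a character into two
regions asserts an independent origin of the structure bearing it, and
costs as much as a transformation.  The applicable/inapplicable
dichotomy is resolved first (one down- and one uppass over the tree,
with ambiguity resolved in favour of presence), then Fitch rules are
applied within applicable regions: three passes score a tree, a fourth
reconstructs ancestral state sets at every vertex.  With no `-` tokens
the score is exactly the Fitch length.

The package is aimed at systematists analysing discrete morphological
matrices (NEXUS or TNT) and at methodologists studying the treatment of
inapplicable data.  It provides:

* the inapplicable-aware scorer and ancestral-state reconstruction
  (`score_character()`, `score_matrix()`, `ancestral_states()`, with the
  individual passes exported);
* the two traditional baselines: gap-as-missing and gap-as-extra-state
  Fitch (`fitch_missing_length()`, `fitch_extra_state_length()`);
* a brute-force labelling oracle for small trees (`min_cost()`,
  `labeling_cost()`);
* a parsimony-ratchet heuristic search under any of the three methods
  (`ratchet_search()`), NNI/SPR rearrangements, and exhaustive search
  for small taxon sets;
* the three-way comparison protocol over sets of optimal trees
  (`cross_score_table()`, `optimal_overlap()`, `consensus_overlap()`);
* a synthetic generator of reductively coded hierarchies
  (`simulate_tree()`, `simulate_hierarchy()`);
* NEXUS / TNT / Newick input and output and a command-line interface
  (`exec/inappfitch`).

## Worked example

A single dependent character on a 12-taxon pectinate tree.  The
principal structure is present in two separate parts of the tree; inside
the first, the character changes from state 1 to state 0; the second
shows an independent occurrence of state 0:

```r
library(inappfitch)

ex <- two_region_example()
tibble::as_tibble(ex$matrix)
#> # A tibble: 12 × 2
#>    taxon char1
#>    <chr> <chr>
#>  1 t1    1
#>  2 t2    1
#>  3 t3    0
#>  4 t4    -
#>  5 t5    -
#>  6 t6    -
#>  7 t7    0
#>  8 t8    0
#>  9 t9    -
#> 10 t10   -
#> 11 t11   -
#> 12 t12   -

score_character(ex$tree, ex$matrix$columns[[1]])
#> score 2 (1 steps + 1 extra regions)
```

One step for the 1 → 0 transformation, one extra region for the
independent second patch of state 0: the character contributes 2 to the
tree score.  The traditional treatments see the same data differently —
`fitch_missing_length()` returns 1 (the second region is free) and
`fitch_extra_state_length()` returns 4 (every excursion into the gap
region is a pseudo-transformation).

Ancestral states from the fourth pass:

```r
ancestral_states(ex$tree, ex$matrix$columns[[1]])$states
#> # A tibble: 23 × 4
#>     node label type     set
#>    <int> <chr> <chr>    <chr>
#>  1     1 t1    tip      {1}
#>  ...
#> 17    17 <NA>  internal {0}
#> 22    22 <NA>  internal {0,1}
#> 23    23 <NA>  internal {1}
```

Vertices outside the two applicable regions are reconstructed `-`; no
logically impossible transformation is implied.

A search-and-compare session:

```r
phy <- simulate_tree(16, seed = 1)
mat <- simulate_hierarchy(phy, hierarchy_spec(n_dependent = 5), seed = 1)

sets <- lapply(c("inapplicable", "missing", "extra_state"), function(m)
  ratchet_search(mat, search_config(m, seed = 1)))
optimal_overlap(sets[[1]], sets[[2]], sets[[3]],
                labels = c("inapplicable", "missing", "extra_state"))
consensus_overlap(sets[[1]], sets[[2]], sets[[3]],
                  labels = c("inapplicable", "missing", "extra_state"))
```

The same operations are available from the shell:

```sh
inappfitch simulate --taxa 16 --seed 1 --out sim
inappfitch score -t sim.nwk -m sim.nex --method inapplicable
inappfitch search -m sim.nex --method inapplicable --seed 1 --out best.nwk
inappfitch oracle -t sim.nwk -m sim.nex --char 2
```

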