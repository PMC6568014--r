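# Brute-force evaluation of the co-minimisation objective (steps + extra
# applicable regions) over fully labelled small trees.  Used as the test
# oracle: the four-pass algorithm is locally optimal, so its total is an
# upper bound on the exhaustive minimum.

#' Cost of one full node labelling
#'
#' Given a single state per vertex (an applicable symbol or the
#' inapplicable token), counts steps (edges whose endpoints hold distinct
#' applicable states; edges touching an inapplicable label cost nothing)
#' and applicable regions (connected components of the subgraph induced by
#' applicable-labelled vertices).  Total = steps + max(0, regions - 1).
#'
#' @param phy Rooted binary `phylo`.
#' @param labeling Character vector over vertices 1..(tips + internals) in
#'   ape node order; each entry an applicable symbol or the inapplicable
#'   token.
#' @param alphabet A [morph_alphabet()] naming the symbols.
#' @return List with `steps`, `regions`, `extra_regions`, `total`.
#' @export
labeling_cost <- function(phy, labeling, alphabet) {
  nv <- length(phy$tip.label) + phy$Nnode
  if (length(labeling) != nv || anyNA(labeling)) {
    stop("labeling must assign one state to each of the ", nv, " vertices",
         call. = FALSE)
  }
  state <- ifelse(labeling == alphabet$inapplicable, 0L,
                  match(labeling, alphabet$applicable))
  if (anyNA(state)) {
    stop("labeling contains symbols outside the alphabet", call. = FALSE)
  }
  sp <- state[phy$edge[, 1]]
  sc <- state[phy$edge[, 2]]
  steps <- sum(sp > 0L & sc > 0L & sp != sc)
  n_app <- sum(state > 0L)
  # induced subgraph of a tree is a forest: components = vertices - edges
  regions <- n_app - sum(sp > 0L & sc > 0L)
  list(steps = steps, regions = regions,
       extra_regions = max(0L, regions - 1L),
       total = steps + max(0L, regions - 1L))
}

# allowed state indices (0 = inapplicable) per vertex, from bit-masks
allowed_states <- function(mask, k) {
  states <- integer(0)
  if (bitwAnd(mask, INAPP_BIT) != 0L) states <- 0L
  for (i in seq_len(k)) {
    if (bitwAnd(mask, bitwShiftL(1L, i)) != 0L) states <- c(states, i)
  }
  states
}

# vectorised minimum labelling cost over the cartesian product of per-node
# allowed state indices; returns min breakdown + an argmin labelling and
# the full vector of totals (for self-consistency checks)
enumerate_labelings <- function(phy, allowed, max_configs = 2e6) {
  nv <- length(allowed)
  n_configs <- prod(vapply(allowed, length, numeric(1)))
  if (n_configs > max_configs) {
    stop("labelling space too large to enumerate (", format(n_configs),
         " > ", format(max_configs), " configurations)", call. = FALSE)
  }
  grid <- as.matrix(expand.grid(allowed, KEEP.OUT.ATTRS = FALSE))
  sp_all <- grid[, phy$edge[, 1], drop = FALSE]
  sc_all <- grid[, phy$edge[, 2], drop = FALSE]
  both_app <- sp_all > 0L & sc_all > 0L
  steps <- rowSums(both_app & sp_all != sc_all)
  regions <- rowSums(grid > 0L) - rowSums(both_app)
  total <- steps + pmax(0L, regions - 1L)
  best <- which.min(total)
  list(steps = steps[best], regions = regions[best],
       extra_regions = max(0L, regions[best] - 1L),
       total = total[best], argmin = grid[best, ], totals = total)
}

#' Exhaustive minimum cost of a character on a small tree
#'
#' Enumerates every assignment of a single state (applicable symbol or the
#' inapplicable token) to each internal node, and every choice within
#' ambiguous tip sets, and minimises [labeling_cost()].  This global
#' minimum is a lower bound on the four-pass algorithm's locally optimal
#' total: the global optimum may connect regions through ancestors in ways
#' the local applicability rules forbid.
#'
#' @param phy Rooted, strictly binary `phylo` (small: the labelling space
#'   must be enumerable).
#' @param column A [morph_column()].
#' @param max_configs Refusal guard on the number of labellings.
#' @return List with `steps`, `regions`, `extra_regions`, `total`, and
#'   `labeling` (an argmin, as symbols).
#' @export
min_cost <- function(phy, column, max_configs = 2e6) {
  assert_binary_rooted(phy)
  column <- column_for_tree(phy, column)
  column <- expand_missing(column, "all_states")
  k <- length(column$alphabet$applicable)
  ntip <- length(phy$tip.label)
  nv <- ntip + phy$Nnode
  allowed <- vector("list", nv)
  for (t in seq_len(ntip)) allowed[[t]] <- allowed_states(column$masks[t], k)
  for (v in (ntip + 1L):nv) allowed[[v]] <- 0L:k
  res <- enumerate_labelings(phy, allowed, max_configs)
  syms <- c(column$alphabet$inapplicable, column$alphabet$applicable)
  res$labeling <- syms[res$argmin + 1L]
  res$totals <- NULL
  res
}

# all labelling costs with states restricted to given per-vertex masks
# (used to check that the final reconstruction attains the reported score)
selection_totals <- function(phy, masks, alphabet, max_configs = 2e6) {
  k <- length(alphabet$applicable)
  allowed <- lapply(masks, allowed_states, k = k)
  enumerate_labelings(phy, allowed, max_configs)$totals
}
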