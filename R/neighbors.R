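# Tree rearrangement engines for the ratchet: nearest-neighbour
# interchange (edge-matrix surgery) and subtree prune-and-regraft (rooted
# prune/regraft swept over all rerootings).  Neighbourhoods are
# deduplicated by canonical unrooted identity and never contain the input
# topology.

#' Nearest-neighbour-interchange neighbourhood
#'
#' All trees one NNI away: two swaps per internal edge of the unrooted
#' topology (an n-leaf binary tree has n - 3 of them, so 2(n - 3)
#' neighbours before deduplication).
#'
#' @param phy Rooted binary `phylo` with at least 4 leaves.
#' @return List of rooted binary `phylo` objects, canonically distinct and
#'   excluding the input topology.
#' @export
nni_neighbors <- function(phy) {
  assert_binary_rooted(phy)
  n <- length(phy$tip.label)
  if (n < 4L) stop("NNI requires at least 4 leaves", call. = FALSE)
  edge <- phy$edge
  root <- n + 1L
  out <- list()
  swap_rows <- function(r1, r2) {
    e2 <- edge
    tmp <- e2[r1, 2L]
    e2[r1, 2L] <- e2[r2, 2L]
    e2[r2, 2L] <- tmp
    t2 <- phy
    t2$edge <- e2
    t2$edge.length <- NULL
    stats::reorder(t2, "cladewise")
  }
  # internal edges away from the root: swap each child of v with v's sibling
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 2L]
    u <- edge[e, 1L]
    if (v <= n || u == root) next
    sib_row <- which(edge[, 1L] == u & edge[, 2L] != v)
    for (kr in which(edge[, 1L] == v)) {
      out[[length(out) + 1L]] <- swap_rows(sib_row[1L], kr)
    }
  }
  # the edge between the root's children (one unrooted edge when both are
  # internal): swap a child of one with a child of the other
  rc <- edge[edge[, 1L] == root, 2L]
  if (all(rc > n)) {
    for (lr in which(edge[, 1L] == rc[1L])) {
      for (rr in which(edge[, 1L] == rc[2L])) {
        out[[length(out) + 1L]] <- swap_rows(lr, rr)
      }
    }
  }
  dedup_trees(out, exclude = canonical_id(phy))
}

dedup_trees <- function(trees, exclude = character(0)) {
  ids <- vapply(trees, canonical_id, character(1))
  keep <- !duplicated(ids) & !(ids %in% exclude)
  trees[keep]
}

# nested-list representation used for SPR surgery ------------------------

phylo_to_list <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(v) {
    if (v <= n) return(phy$tip.label[v])
    lapply(kids[[as.character(v)]], build)
  }
  build(n + 1L)
}

list_to_newick <- function(x) {
  render <- function(v) {
    if (is.character(v)) return(v)
    paste0("(", paste(vapply(v, render, character(1)), collapse = ","), ")")
  }
  paste0(render(x), ";")
}

list_to_phylo <- function(x) parse_newick(list_to_newick(x))

# every internal position in the nested list, as an index path
node_paths <- function(x, path = integer(0)) {
  if (is.character(x)) return(list(path))
  out <- list(path)
  for (i in seq_along(x)) {
    out <- c(out, node_paths(x[[i]], c(path, i)))
  }
  out
}

subtree_at <- function(x, path) if (length(path) == 0L) x else
  subtree_at(x[[path[1L]]], path[-1L])

replace_at <- function(x, path, value) {
  if (length(path) == 0L) return(value)
  x[[path[1L]]] <- replace_at(x[[path[1L]]], path[-1L], value)
  x
}

# prune the subtree at `path` (length >= 1) from a binary nested list,
# suppressing the degree-2 node left behind; returns list(pruned, rest)
prune_at <- function(x, path) {
  pruned <- subtree_at(x, path)
  parent_path <- path[-length(path)]
  parent <- subtree_at(x, parent_path)
  sibling <- parent[[setdiff(1:2, path[length(path)])]]
  list(pruned = pruned, rest = replace_at(x, parent_path, sibling))
}

# regraft `sub` onto every edge of `rest` (each node position = the edge
# above it), and above the root
regraft_everywhere <- function(rest, sub) {
  sites <- node_paths(rest)
  lapply(sites, function(p) {
    if (length(p) == 0L) list(rest, sub)
    else replace_at(rest, p, list(subtree_at(rest, p), sub))
  })
}

#' Subtree-prune-and-regraft neighbourhood
#'
#' All trees one SPR away in the unrooted sense: every subtree is pruned
#' and regrafted onto every other edge, with the tree rerooted on every
#' edge first so that both directions of each pruning edge are covered.
#' A superset of [nni_neighbors()].
#'
#' @inheritParams nni_neighbors
#' @return List of rooted binary `phylo` objects, canonically distinct and
#'   excluding the input topology.
#' @export
spr_neighbors <- function(phy) {
  assert_binary_rooted(phy)
  if (length(phy$tip.label) < 4L) {
    stop("SPR requires at least 4 leaves", call. = FALSE)
  }
  out <- list()
  for (r in all_rerootings(phy)) {
    x <- phylo_to_list(r)
    for (path in node_paths(x)) {
      if (length(path) == 0L) next     # cannot prune the whole tree
      pr <- prune_at(x, path)
      if (is.character(pr$rest)) next  # nothing left to regraft onto
      for (y in regraft_everywhere(pr$rest, pr$pruned)) {
        out[[length(out) + 1L]] <- y
      }
    }
  }
  # deduplicate on newick strings first to avoid converting thousands
  keys <- vapply(out, list_to_newick, character(1))
  out <- out[!duplicated(keys)]
  trees <- lapply(out, list_to_phylo)
  dedup_trees(trees, exclude = canonical_id(phy))
}
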