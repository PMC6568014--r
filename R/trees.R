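# Trees are ape "phylo" objects throughout.  Scoring requires rooted,
# strictly binary trees; parsing accepts polytomies, which can be resolved
# explicitly with resolve_polytomies().

#' Parse a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the text and
#' rejects duplicated leaf labels.  Edge lengths and internal labels are
#' parsed but ignored by all scoring functions.
#'
#' @param text Newick string (terminating semicolon required).
#' @return A `phylo` object.
#' @export
parse_newick <- function(text) {
  if (!grepl(";", text)) stop("Newick text lacks a terminating ';'",
                              call. = FALSE)
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick text", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicated leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1], call. = FALSE)
  }
  phy
}

#' Write a tree as Newick
#' @param phy A `phylo` object.
#' @return Newick string.
#' @export
write_newick <- function(phy) ape::write.tree(phy)

#' Read / write multi-tree Newick files (one tree per line)
#' @param file Path to a Newick file.
#' @return `read_trees`: a `multiPhylo` list of trees.
#' @export
read_trees <- function(file) {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}

#' @rdname read_trees
#' @param trees A list of `phylo` objects (or `multiPhylo`).
#' @export
write_trees <- function(trees, file) {
  writeLines(vapply(trees, ape::write.tree, character(1)), file)
  invisible(file)
}

is_binary_rooted <- function(phy) {
  ape::is.rooted(phy) && ape::is.binary(phy)
}

assert_binary_rooted <- function(phy) {
  if (!is_binary_rooted(phy)) {
    stop("scoring requires a rooted, strictly binary tree; ",
         "see resolve_polytomies()", call. = FALSE)
  }
  invisible(phy)
}

#' Resolve polytomies at random
#'
#' Randomly refines every polytomy into a binary subtree.  Random rather
#' than silent arbitrary resolution, because the scoring rules are defined
#' for exactly two descendants per node.
#'
#' @param phy A `phylo` object.
#' @param seed Integer seed controlling the resolution.
#' @return A rooted binary `phylo`.
#' @export
resolve_polytomies <- function(phy, seed = 1L) {
  with_seed(seed, {
    out <- ape::multi2di(phy, random = TRUE)
    if (!ape::is.rooted(out)) out <- ape::root(out, 1L, resolve.root = TRUE)
    out
  })
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reroot a tree on a given edge
#'
#' The root is placed so that it subdivides the chosen edge of the
#' unrooted topology; the unrooted topology (and hence the bipartition set
#' and any parsimony score) is unchanged.
#'
#' @param phy A `phylo` object.
#' @param edge Row index into the edge matrix of `ape::unroot(phy)`.
#' @return A rooted binary `phylo`.
#' @seealso [all_rerootings()]
#' @export
reroot_at_edge <- function(phy, edge) {
  u <- ape::unroot(phy)
  if (!is.numeric(edge) || edge < 1L || edge > nrow(u$edge)) {
    stop("edge index out of range (tree has ", nrow(u$edge), " edges)",
         call. = FALSE)
  }
  child <- u$edge[edge, 2L]
  n <- length(u$tip.label)
  out_tips <- if (child <= n) u$tip.label[child] else
    u$tip.label[clade_tips(u, child)]
  r <- ape::root(u, outgroup = out_tips, resolve.root = TRUE)
  r
}

# tip indices below an internal node of a phylo
clade_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    v <- todo[1]; todo <- todo[-1]
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    tips <- c(tips, kids[kids <= n])
    todo <- c(todo, kids[kids > n])
  }
  tips
}

#' All distinct rerootings of a tree
#'
#' One rooted tree per edge of the unrooted topology (an unrooted binary
#' tree with n leaves has 2n - 3 of them).
#'
#' @param phy A `phylo` object.
#' @return List of rooted binary `phylo` objects.
#' @export
all_rerootings <- function(phy) {
  u <- ape::unroot(phy)
  lapply(seq_len(nrow(u$edge)), function(e) reroot_at_edge(u, e))
}

#' Nontrivial bipartitions of a tree
#'
#' Each internal edge of the unrooted topology splits the leaf set in two;
#' splits are canonicalised by storing the side that does not contain the
#' lexicographically first taxon, as a sorted comma-separated string.
#' Trivial splits (single leaf or its complement) are excluded; a binary
#' n-leaf tree yields n - 3 of them.
#'
#' @param phy A `phylo` object.
#' @return Character vector (a set) of canonical split strings.
#' @export
bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  if (n < 4L) return(character(0))
  u <- ape::unroot(phy)
  ref <- sort(u$tip.label)[1]
  out <- character(0)
  for (e in seq_len(nrow(u$edge))) {
    child <- u$edge[e, 2L]
    if (child <= n) next
    side <- sort(u$tip.label[clade_tips(u, child)])
    if (ref %in% side) side <- sort(setdiff(u$tip.label, side))
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(side, collapse = ","))
  }
  sort(unique(out))
}

#' Canonical identity of an unrooted topology
#'
#' Two trees get the same identity string iff they are the same unrooted
#' topology on the same leaf set, regardless of rooting.  Used to
#' deduplicate trees in searches and optimal-set tallies.
#'
#' @param phy A `phylo` object.
#' @return Character scalar.
#' @export
canonical_id <- function(phy) {
  paste(c(paste(sort(phy$tip.label), collapse = ","), bipartitions(phy)),
        collapse = ";")
}

#' Strict consensus tree
#'
#' The tree whose bipartitions are exactly those present in every input
#' tree (may contain polytomies).
#'
#' @param trees List of `phylo` objects (or `multiPhylo`) on one leaf set.
#' @return An unrooted `phylo`.
#' @export
strict_consensus <- function(trees) {
  trees <- if (inherits(trees, "phylo")) list(trees) else as.list(trees)
  if (length(trees) == 0L) stop("empty tree set", call. = FALSE)
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets, identical, logical(1), leafsets[[1]]))) {
    stop("trees do not share one leaf set", call. = FALSE)
  }
  if (length(trees) == 1L) return(ape::unroot(trees[[1]]))
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}
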