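# Heuristic maximum-parsimony search under any of the three treatments of
# inapplicable tokens: hill climbing with NNI (or SPR) rearrangements,
# wrapped in a parsimony ratchet -- alternating climbs under perturbed
# character weights (a random fraction of characters doubled) and the
# original weights, to escape local optima.

#' Search configuration
#'
#' @param method `"inapplicable"`, `"missing"` or `"extra_state"`.
#' @param ratchet_iterations Maximum number of ratchet iterations.
#' @param perturb_fraction Fraction of characters whose weight is doubled
#'   in the perturbed phase (strictly between 0 and 1).
#' @param rearrangement `"nni"` or `"spr"`.
#' @param seed Integer seed; the whole search is reproducible given it.
#' @param stop_after_no_improvement Stop once the incumbent best score has
#'   survived this many consecutive ratchet iterations.
#' @param max_trees Cap on the number of equal-best topologies retained.
#' @return A `search_config` list.
#' @export
search_config <- function(method = c("inapplicable", "missing",
                                     "extra_state"),
                          ratchet_iterations = 250L,
                          perturb_fraction = 0.25,
                          rearrangement = c("nni", "spr"),
                          seed = 1L,
                          stop_after_no_improvement = 250L,
                          max_trees = 10000L) {
  method <- match.arg(method)
  rearrangement <- match.arg(rearrangement)
  stopifnot(ratchet_iterations >= 1L,
            perturb_fraction > 0, perturb_fraction < 1,
            stop_after_no_improvement >= 1L)
  structure(list(method = method,
                 ratchet_iterations = as.integer(ratchet_iterations),
                 perturb_fraction = perturb_fraction,
                 rearrangement = rearrangement, seed = as.integer(seed),
                 stop_after_no_improvement =
                   as.integer(stop_after_no_improvement),
                 max_trees = as.integer(max_trees)),
            class = "search_config")
}

#' Random-addition starting tree
#'
#' Builds a rooted binary tree by adding taxa in random order onto random
#' edges (stepwise addition).
#'
#' @param taxa Character vector of taxon labels (>= 3).
#' @return Rooted binary `phylo`.
#' @export
random_addition_tree <- function(taxa) {
  stopifnot(length(taxa) >= 3L)
  ord <- sample(taxa)
  x <- list(ord[1], list(ord[2], ord[3]))
  for (t in ord[-(1:3)]) {
    sites <- node_paths(x)
    sites <- sites[vapply(sites, length, integer(1)) > 0L]
    p <- sites[[sample.int(length(sites), 1L)]]
    x <- replace_at(x, p, list(subtree_at(x, p), t))
  }
  list_to_phylo(x)
}

neighbor_fun <- function(rearrangement) {
  switch(rearrangement, nni = nni_neighbors, spr = spr_neighbors)
}

# greedy hill climb: move to the best strictly improving neighbour until a
# local optimum is reached
hill_climb <- function(phy, scorefun, nbrs) {
  s <- scorefun(phy)
  repeat {
    cand <- nbrs(phy)
    if (length(cand) == 0L) return(list(tree = phy, score = s))
    cs <- vapply(cand, scorefun, numeric(1))
    if (min(cs) >= s) return(list(tree = phy, score = s))
    i <- which.min(cs)
    phy <- cand[[i]]
    s <- cs[i]
  }
}

# breadth-first exploration of the equal-score plateau around `tree`,
# collecting distinct topologies; restarts if a better tree is met
collect_plateau <- function(tree, score, scorefun, nbrs, max_trees) {
  repeat {
    seen <- stats::setNames(list(tree), canonical_id(tree))
    queue <- list(tree)
    overflow <- FALSE
    improved <- NULL
    while (length(queue) > 0L && is.null(improved)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (nb in nbrs(cur)) {
        id <- canonical_id(nb)
        if (!is.null(seen[[id]])) next
        s <- scorefun(nb)
        if (s < score) { improved <- list(tree = nb, score = s); break }
        if (s > score) next
        if (length(seen) >= max_trees) { overflow <- TRUE; next }
        seen[[id]] <- nb
        queue[[length(queue) + 1L]] <- nb
      }
    }
    if (is.null(improved)) {
      return(list(trees = unname(seen), ids = names(seen), score = score,
                  overflow = overflow))
    }
    hc <- hill_climb(improved$tree, scorefun, nbrs)
    tree <- hc$tree
    score <- hc$score
  }
}

#' Parsimony ratchet tree search
#'
#' Searches for minimum-score trees under the chosen treatment of
#' inapplicable tokens.  Starting from a random-addition tree, the search
#' alternates hill climbing under perturbed character weights (a random
#' `perturb_fraction` of characters doubled) with hill climbing under the
#' original weights, and finally collects all distinct topologies on the
#' equal-score plateau of the best tree.  Terminates when the incumbent
#' best score has survived `stop_after_no_improvement` consecutive ratchet
#' iterations, or when `ratchet_iterations` is exhausted.  Bit-reproducible
#' given `config$seed`.
#'
#' @param matrix A [morph_matrix()].
#' @param config A [search_config()].
#' @return An object of class `tree_set`: `trees` (list of rooted binary
#'   `phylo`), `score` (best score found), `method`, `overflow` flag, and
#'   the per-iteration `score_log`.
#' @export
ratchet_search <- function(matrix, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  ncharx <- length(matrix$columns)
  w0 <- rep(1, ncharx)
  scorefun <- function(w) {
    force(w)
    function(phy) score_matrix(phy, matrix, config$method, weights = w)$total
  }
  s0 <- scorefun(w0)
  nbrs <- neighbor_fun(config$rearrangement)
  with_seed(config$seed, {
    start <- random_addition_tree(matrix$taxa)
    hc <- hill_climb(start, s0, nbrs)
    current <- best_tree <- hc$tree
    best <- hc$score
    log <- best
    stale <- 0L
    for (i in seq_len(config$ratchet_iterations)) {
      if (stale >= config$stop_after_no_improvement) break
      nperturb <- max(1L, round(config$perturb_fraction * ncharx))
      w <- w0
      w[sample.int(ncharx, nperturb)] <- 2
      # perturbed phase drifts from the current tree (not the incumbent
      # best), seeded by a random neighbour so flat perturbations still
      # move the search
      cand <- nbrs(current)
      seed_tree <- if (length(cand)) cand[[sample.int(length(cand), 1L)]]
                   else current
      t1 <- hill_climb(seed_tree, scorefun(w), nbrs)$tree
      hc <- hill_climb(t1, s0, nbrs)
      current <- hc$tree
      if (hc$score < best) {
        best <- hc$score
        best_tree <- hc$tree
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      log <- c(log, best)
    }
    plateau <- collect_plateau(best_tree, best, s0, nbrs, config$max_trees)
    structure(list(trees = plateau$trees, ids = plateau$ids,
                   score = plateau$score, method = config$method,
                   overflow = plateau$overflow, score_log = log,
                   config = config),
              class = "tree_set")
  })
}

#' @export
print.tree_set <- function(x, ...) {
  cat("<tree_set> ", length(x$trees), " optimal topolog",
      if (length(x$trees) == 1L) "y" else "ies",
      ", method '", x$method, "', score ", x$score,
      if (x$overflow) " (tree cap hit)", "\n", sep = "")
  invisible(x)
}

#' @rdname ratchet_search
#' @param x A `tree_set`.
#' @param ... Unused.
#' @method glance tree_set
#' @export
glance.tree_set <- function(x, ...) {
  tibble::tibble(method = x$method, score = x$score,
                 n_trees = length(x$trees), overflow = x$overflow,
                 iterations = length(x$score_log) - 1L)
}

#' Exhaustive search over all unrooted topologies
#'
#' Enumerates every unrooted binary topology on the matrix's taxa
#' (feasible for about 9 or fewer) and returns all trees attaining the
#' minimum score.  Used as ground truth for the heuristic search.
#'
#' @param matrix A [morph_matrix()].
#' @param method `"inapplicable"`, `"missing"` or `"extra_state"`.
#' @param max_taxa Refusal guard.
#' @return A `tree_set`.
#' @export
exhaustive_search <- function(matrix,
                              method = c("inapplicable", "missing",
                                         "extra_state"),
                              max_taxa = 9L) {
  method <- match.arg(method)
  if (length(matrix$taxa) > max_taxa) {
    stop("too many taxa for exhaustive enumeration", call. = FALSE)
  }
  trees <- all_topologies(matrix$taxa)
  scores <- vapply(trees, function(t) score_matrix(t, matrix, method)$total,
                   numeric(1))
  best <- min(scores)
  keep <- trees[scores == best]
  structure(list(trees = keep,
                 ids = vapply(keep, canonical_id, character(1)),
                 score = best, method = method, overflow = FALSE,
                 score_log = best, config = NULL),
            class = "tree_set")
}

#' All unrooted binary topologies on a taxon set
#'
#' Sequential-addition enumeration: (2n - 5)!! topologies for n taxa,
#' returned as rooted binary `phylo` objects (one arbitrary rooting each).
#'
#' @param taxa Character vector of at least 3 taxon labels.
#' @return List of rooted binary `phylo` objects.
#' @export
all_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3L)
  # fix taxa[1] as the stem: an unrooted tree on n taxa corresponds
  # one-to-one to a rooted tree on the remaining n - 1, with insertion
  # allowed on every edge including the stem (the empty path)
  grow <- function(x, remaining) {
    if (length(remaining) == 0L) return(list(x))
    t <- remaining[1]
    out <- list()
    for (p in node_paths(x)) {
      out <- c(out, grow(replace_at(x, p, list(subtree_at(x, p), t)),
                         remaining[-1]))
    }
    out
  }
  lapply(grow(list(taxa[2], taxa[3]), taxa[-(1:3)]),
         function(x) list_to_phylo(list(taxa[1], x)))
}
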