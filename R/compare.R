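# Three-way comparison of optimal tree sets: cross-scoring one method's
# optimal trees under another method, Venn tallies of canonically distinct
# topologies, and shared-bipartition fractions between strict consensus
# trees.

as_tree_list <- function(x) {
  if (inherits(x, "tree_set")) x$trees
  else if (inherits(x, "phylo")) list(x)
  else as.list(x)
}

set_ids <- function(x) {
  if (inherits(x, "tree_set")) x$ids
  else vapply(as_tree_list(x), canonical_id, character(1))
}

#' Cross-score one method's optimal trees under another method
#'
#' Scores every tree of `treesP` under `methodQ` and reports each score
#' relative to the minimum `methodQ` score over `treesP` and (when given)
#' `treesQ`, so that 0 means the topology is also optimal under Q.
#' Relative rather than absolute scores are reported because the three
#' methods' absolute scales differ.
#'
#' @param treesP A `tree_set`, `multiPhylo`, or list of trees.
#' @param matrix A [morph_matrix()].
#' @param methodQ Scoring method to evaluate under.
#' @param treesQ Optional reference set (typically methodQ's optimal
#'   trees) included when taking the minimum.
#' @return Tibble with columns `tree` (canonical id), `score`,
#'   `relative_score`.
#' @export
cross_score_table <- function(treesP, matrix,
                              methodQ = c("inapplicable", "missing",
                                          "extra_state"),
                              treesQ = NULL) {
  methodQ <- match.arg(methodQ)
  tp <- as_tree_list(treesP)
  for (t in tp) {
    if (!setequal(t$tip.label, matrix$taxa)) {
      stop("tree taxa do not match the matrix", call. = FALSE)
    }
  }
  sc <- function(t) score_matrix(t, matrix, methodQ)$total
  scores <- vapply(tp, sc, numeric(1))
  ref <- scores
  if (!is.null(treesQ)) {
    ref <- c(ref, vapply(as_tree_list(treesQ), sc, numeric(1)))
  }
  out <- tibble::tibble(tree = set_ids(treesP), score = scores,
                        relative_score = scores - min(ref))
  class(out) <- c("cross_score_table", class(out))
  out
}

#' Plot a cross-score distribution
#'
#' Histogram of relative scores from [cross_score_table()]: the
#' distribution of scores that trees optimal under method P attain under
#' method Q, relative to Q's minimum.
#'
#' @param object A tibble from [cross_score_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cross_score_table
#' @export
autoplot.cross_score_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$relative_score)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35",
                            colour = "white") +
    ggplot2::labs(x = "score relative to method Q's minimum",
                  y = "trees") +
    ggplot2::theme_minimal()
}

#' @rdname cross_score_table
#' @param x A tibble from [cross_score_table()].
#' @param ... Unused.
#' @export
plot_cross_scores <- function(x, ...) autoplot.cross_score_table(x, ...)

#' Venn tally of topologies optimal under one, two or three methods
#'
#' Counts canonically distinct topologies occurring in the optimal sets of
#' exactly one, exactly two (each pair), or all three methods.
#'
#' @param setA,setB,setC `tree_set`s (or tree lists) for the three
#'   methods.
#' @param labels Names of the three methods.
#' @return Tibble with columns `region`, `count`, `proportion`; the counts
#'   sum to the size of the union of the three sets.
#' @export
optimal_overlap <- function(setA, setB, setC,
                            labels = c("A", "B", "C")) {
  a <- unique(set_ids(setA)); b <- unique(set_ids(setB))
  c_ <- unique(set_ids(setC))
  all_ids <- unique(c(a, b, c_))
  inA <- all_ids %in% a; inB <- all_ids %in% b; inC <- all_ids %in% c_
  key <- paste0(ifelse(inA, "1", "0"), ifelse(inB, "1", "0"),
                ifelse(inC, "1", "0"))
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  region_labels <- c(paste0(labels[1], "_only"), paste0(labels[2], "_only"),
                     paste0(labels[3], "_only"),
                     paste(labels[1], labels[2], sep = "+"),
                     paste(labels[1], labels[3], sep = "+"),
                     paste(labels[2], labels[3], sep = "+"),
                     paste(labels, collapse = "+"))
  counts <- unname(vapply(regions, function(r) sum(key == r), integer(1)))
  tibble::tibble(region = region_labels, count = counts,
                 proportion = if (length(all_ids)) counts / length(all_ids)
                              else rep(NA_real_, 7L))
}

#' Shared-bipartition fractions between strict consensus trees
#'
#' For each ordered pair of optimal sets (X, Y): the fraction of the
#' bipartitions present in every tree optimal under X (i.e. in X's strict
#' consensus) that are also present in every tree optimal under Y; plus,
#' per set, the fraction of its consensus bipartitions present in all
#' three consensuses.  `NA` when a consensus is star-shaped (no
#' bipartitions to take a fraction of).
#'
#' @inheritParams optimal_overlap
#' @return Tibble with columns `from`, `to` (`"all"` for the triple
#'   fraction), `shared`, `of`, `fraction`.
#' @export
consensus_overlap <- function(setA, setB, setC,
                              labels = c("A", "B", "C")) {
  sets <- list(as_tree_list(setA), as_tree_list(setB), as_tree_list(setC))
  if (any(vapply(sets, length, integer(1)) == 0L)) {
    stop("empty tree set", call. = FALSE)
  }
  splits <- lapply(sets, function(s) bipartitions(strict_consensus(s)))
  rows <- list()
  for (i in 1:3) {
    for (j in setdiff(1:3, i)) {
      n_i <- length(splits[[i]])
      shared <- length(intersect(splits[[i]], splits[[j]]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = labels[i], to = labels[j], shared = shared, of = n_i,
        fraction = if (n_i == 0L) NA_real_ else shared / n_i)
    }
  }
  triple <- Reduce(intersect, splits)
  for (i in 1:3) {
    n_i <- length(splits[[i]])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      from = labels[i], to = "all", shared = length(triple), of = n_i,
      fraction = if (n_i == 0L) NA_real_ else length(triple) / n_i)
  }
  do.call(rbind, rows)
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
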