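# Synthetic generator of trees and reductively coded character
# hierarchies: a principal presence/absence character evolves on the tree
# by a two-state continuous-time chain, and each dependent character
# evolves by a symmetric chain along the lineages where the principal
# structure is present, being emitted as the gap token at tips where it is
# absent.  The generator reproduces the coding structure the scoring
# algorithm assumes -- it makes no claim to realistic morphological
# evolution.

#' Specification of a simulated character hierarchy
#'
#' @param n_dependent Number of dependent (contingent) characters.
#' @param n_dependent_states States per dependent transformational
#'   character (2 when `neomorphic_dependent`).
#' @param gain_rate,loss_rate Principal-character gain (0 to 1) and loss
#'   (1 to 0) rates per unit branch length.
#' @param dependent_rate Total change rate of each dependent character
#'   along applicable lineages.
#' @param missing_rate Probability that any cell is replaced by the
#'   missing token.
#' @param neomorphic_dependent If `TRUE` dependent characters are binary
#'   presence/absence (neomorphic) characters, which [recode_neomorphic()]
#'   can convert to additive-binary coding.
#' @return A `hierarchy_spec` list.
#' @export
hierarchy_spec <- function(n_dependent = 3L, n_dependent_states = 2L,
                           gain_rate = 0.3, loss_rate = 0.3,
                           dependent_rate = 0.5, missing_rate = 0,
                           neomorphic_dependent = FALSE) {
  stopifnot(gain_rate > 0, loss_rate > 0, dependent_rate > 0,
            missing_rate >= 0, missing_rate < 1,
            n_dependent >= 1L, n_dependent_states >= 2L)
  if (neomorphic_dependent) n_dependent_states <- 2L
  structure(list(n_dependent = as.integer(n_dependent),
                 n_dependent_states = as.integer(n_dependent_states),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 dependent_rate = dependent_rate,
                 missing_rate = missing_rate,
                 neomorphic_dependent = neomorphic_dependent),
            class = "hierarchy_spec")
}

#' Simulate a random tree
#'
#' Yule (pure-birth) topology: starting from two lineages, a uniformly
#' chosen extant lineage splits until `n_taxa` leaves exist.  Unit branch
#' lengths.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param seed Integer seed.
#' @return Rooted binary `phylo` with tips `t1..tn` and unit edge lengths.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4", call. = FALSE)
  with_seed(seed, {
    x <- list("t1", "t2")
    for (i in 3:n_taxa) {
      leaves <- node_paths(x)
      leaves <- leaves[vapply(leaves, function(p) {
        length(p) > 0L && is.character(subtree_at(x, p))
      }, logical(1))]
      p <- leaves[[sample.int(length(leaves), 1L)]]
      x <- replace_at(x, p, list(subtree_at(x, p), paste0("t", i)))
    }
    phy <- list_to_phylo(x)
    phy$edge.length <- rep(1, nrow(phy$edge))
    phy
  })
}

# exact CTMC path of the 2-state principal character along one branch:
# returns the durations spent in each state plus the end state, as a list
# of segments (state, length)
principal_branch_path <- function(state, len, gain, loss) {
  segs <- list()
  t <- 0
  while (t < len) {
    rate <- if (state == 1L) loss else gain
    wait <- stats::rexp(1L, rate)
    dur <- min(wait, len - t)
    segs[[length(segs) + 1L]] <- c(state = state, dur = dur)
    if (wait < len - t) state <- 1L - state
    t <- t + dur
  }
  list(segs = segs, end = state)
}

# evolve one dependent character along a principal path; symmetric k-state
# chain active only while the principal structure is present; a fresh
# uniform state is drawn at each independent gain
dependent_along_path <- function(state, segs, rate, k) {
  for (seg in segs) {
    if (seg[["state"]] == 1L) {
      if (is.na(state)) state <- sample.int(k, 1L)   # independent origin
      n_changes <- stats::rpois(1L, rate * seg[["dur"]])
      for (i in seq_len(n_changes)) {
        state <- sample(setdiff(seq_len(k), state), 1L)
      }
    } else {
      state <- NA_integer_
    }
  }
  state
}

#' Simulate a reductively coded character hierarchy
#'
#' Evolves a principal binary presence/absence character along the tree,
#' then `n_dependent` dependent characters along the applicable lineages
#' only; tips where the principal structure is absent carry the gap token
#' in every dependent character.  The principal structure is present at
#' the root.  With `missing_rate > 0`, cells are independently replaced by
#' the missing token after coding.
#'
#' @param phy Rooted binary `phylo` with edge lengths (unit lengths
#'   assumed when absent).
#' @param spec A [hierarchy_spec()].
#' @param seed Integer seed.
#' @return A [morph_matrix()] whose first column is the principal
#'   character; the generating tree is attached as attribute `true_tree`.
#' @export
simulate_hierarchy <- function(phy, spec = hierarchy_spec(), seed = 1L) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  assert_binary_rooted(phy)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  ntip <- length(phy$tip.label)
  nv <- ntip + phy$Nnode
  with_seed(seed, {
    # one principal realisation shared by all dependents
    paths <- vector("list", nrow(phy$edge))
    principal <- integer(nv)
    principal[ntip + 1L] <- 1L          # structure present ancestrally
    pre <- rev(unique(stats::reorder(phy, "postorder")$edge[, 1]))
    edge_rows_of <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
    for (v in pre) {
      for (e in edge_rows_of[[as.character(v)]]) {
        p <- principal_branch_path(principal[phy$edge[e, 1]],
                                   phy$edge.length[e],
                                   spec$gain_rate, spec$loss_rate)
        paths[[e]] <- p$segs
        principal[phy$edge[e, 2]] <- p$end
      }
    }
    k <- spec$n_dependent_states
    dep_tips <- matrix(NA_integer_, ntip, spec$n_dependent)
    for (j in seq_len(spec$n_dependent)) {
      dep <- integer(nv)
      dep[ntip + 1L] <- sample.int(k, 1L)
      for (v in pre) {
        for (e in edge_rows_of[[as.character(v)]]) {
          from <- phy$edge[e, 1]; to <- phy$edge[e, 2]
          s <- dependent_along_path(
            if (principal[from] == 1L) dep[from] else NA_integer_,
            paths[[e]], spec$dependent_rate, k)
          dep[to] <- if (is.na(s)) NA_integer_ else s
        }
      }
      dep_tips[, j] <- dep[seq_len(ntip)]
    }
    symbols <- as.character(0:(k - 1L))
    cells <- matrix("", ntip, 1L + spec$n_dependent)
    cells[, 1] <- as.character(principal[seq_len(ntip)])
    for (j in seq_len(spec$n_dependent)) {
      cells[, j + 1L] <- ifelse(is.na(dep_tips[, j]), "-",
                                symbols[dep_tips[, j]])
    }
    if (spec$missing_rate > 0) {
      hit <- matrix(stats::runif(length(cells)) < spec$missing_rate,
                    nrow(cells))
      cells[hit] <- "?"
    }
    taxa <- phy$tip.label
    cell_list <- stats::setNames(lapply(seq_len(ntip), function(i) {
      as.list(cells[i, ])
    }), taxa)
    labels <- c("principal", paste0("dependent", seq_len(spec$n_dependent)))
    cols <- columns_from_cells(taxa, cell_list, "?", "-", labels = labels)
    m <- morph_matrix(taxa, cols)
    attr(m, "true_tree") <- phy
    m
  })
}
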