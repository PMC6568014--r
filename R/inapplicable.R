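# Four-pass single-character parsimony with an inapplicable state.
#
# The tree score of a character is steps + extra applicable regions:
# a transformation between two applicable states costs one step, and every
# additional region of character applicability beyond the first costs one
# region.  Pass 1 (downpass) and pass 2 (uppass + tip resolution) resolve
# each vertex as applicable or inapplicable; pass 3 (downpass) applies
# Fitch rules within applicable regions, counts steps, and uses a per-node
# "tracker" (does this subtree contain an applicable region?) to count the
# junctions where two separate applicable regions meet; pass 4 (uppass)
# finalises ancestral state sets and never changes the score.

#' Per-character working record for the four passes
#'
#' Builds the node-indexed storage on which [first_downpass()],
#' [first_uppass()], [resolve_tips()], [second_downpass()] and
#' [second_uppass()] operate.  Missing cells are expanded (all applicable
#' states plus the inapplicable state) if the column still carries missing
#' markers.
#'
#' @param phy Rooted, strictly binary `phylo` whose tips are all present in
#'   the column.
#' @param column A [morph_column()].
#' @return An object of class `inapp_record`: node-indexed state vectors
#'   (`down`, `up`, `work`, `final`), the applicability `flag` and region
#'   `tracker`, and the running `steps` / `regions` counts.
#' @export
character_record <- function(phy, column) {
  assert_binary_rooted(phy)
  idx <- match(phy$tip.label, names(column$masks))
  if (anyNA(idx)) {
    stop("taxon '", phy$tip.label[which(is.na(idx))[1]],
         "' is absent from the character", call. = FALSE)
  }
  if (any(column$missing)) column <- expand_missing(column, "all_states")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  nv <- ntip + nnode
  edge <- phy$edge
  parent <- integer(nv)
  parent[edge[, 2]] <- edge[, 1]
  po <- stats::reorder(phy, "postorder")
  porder <- unique(po$edge[, 1])          # internal nodes, children first
  kids <- matrix(0L, 2L, nv)
  for (v in porder) {
    ch <- edge[edge[, 1] == v, 2]
    kids[, v] <- ch
  }
  structure(list(
    phy = phy, ntip = ntip, nv = nv, root = ntip + 1L,
    parent = parent, kids = kids, porder = porder,
    alphabet = column$alphabet, app = app_mask(column$alphabet),
    tipmask = stats::setNames(column$masks[idx], phy$tip.label),
    down = integer(nv), up = integer(nv), above = integer(nv),
    flag = logical(nv),
    resolved = integer(nv), work = integer(nv), final = integer(nv),
    tracker = logical(nv), steps = 0L, regions = 0L,
    stage = "init"
  ), class = "inapp_record")
}

#' @export
print.inapp_record <- function(x, ...) {
  cat("<inapp_record> ", x$ntip, " tips, stage '", x$stage,
      "', steps ", x$steps, ", extra regions ", x$regions, "\n", sep = "")
  invisible(x)
}

# downpass combine rule for two directed state sets
merge_down <- function(l, r, app) {
  l_app <- bitwAnd(l, app) != 0L
  r_app <- bitwAnd(r, app) != 0L
  l_in <- bitwAnd(l, INAPP_BIT) != 0L
  r_in <- bitwAnd(r, INAPP_BIT) != 0L
  if (l_app && r_app && !(l_in && r_in)) {
    common <- bitwAnd(bitwAnd(l, r), app)
    if (common != 0L) common else bitwAnd(bitwOr(l, r), app)
  } else if (l_in && r_in && !(l_app && r_app)) {
    INAPP_BIT
  } else {
    bitwOr(l, r)
  }
}

#' First downpass: preliminary applicability sets
#'
#' Post-order pass.  At a node with child sets L and R: if both children
#' carry applicable states and at most one carries the inapplicable state,
#' the node takes the shared applicable states (or, when none are shared,
#' all applicable states of both children); otherwise, if both children
#' carry the inapplicable state and at most one carries an applicable
#' state, the node is the inapplicable singleton; otherwise the node takes
#' the union of all descendant states, applicable and inapplicable.
#'
#' @param rec An [character_record()].
#' @return The record with `down` filled.
#' @export
first_downpass <- function(rec) {
  app <- rec$app
  down <- rec$down
  down[seq_len(rec$ntip)] <- rec$tipmask
  for (v in rec$porder) {
    down[v] <- merge_down(down[rec$kids[1L, v]], down[rec$kids[2L, v]], app)
  }
  rec$down <- down
  rec$stage <- "down1"
  rec
}

#' First uppass: resolve each node as applicable or inapplicable
#'
#' Pre-order pass over the three branches incident to each vertex.  The
#' state set entering a vertex from above is computed with the same
#' combine rule as the downpass (`above(v) = merge(above(parent),
#' sibling's preliminary set)`; for the root's children it is simply the
#' other child's preliminary set), so each vertex sees the true directed
#' set on all three of its branches regardless of where the root happens
#' to lie.  A vertex is resolved applicable iff at least two of its three
#' incident sets (from above; the two children's preliminary sets) carry
#' applicable states -- parallel losses are preferred over loss and regain.
#' The root's phantom ancestor counts as applicable for the root vertex
#' itself but is not propagated into the directed sets.  Applicable nodes
#' take the applicable part of their preliminary set, falling back to
#' their children's (then the above-set's) applicable states if that part
#' is empty; inapplicable nodes take the inapplicable singleton.
#'
#' @param rec Record after [first_downpass()].
#' @return The record with `up`, `above` and `flag` filled.
#' @export
first_uppass <- function(rec) {
  app <- rec$app
  down <- rec$down
  up <- rec$up
  above <- rec$above
  flag <- rec$flag
  for (v in rev(rec$porder)) {
    kl <- rec$kids[1L, v]; kr <- rec$kids[2L, v]
    if (v == rec$root) {
      above[kl] <- down[kr]
      above[kr] <- down[kl]
      anc_app <- TRUE                  # phantom ancestor is applicable
      anc_set <- app
    } else {
      above[kl] <- merge_down(above[v], down[kr], app)
      above[kr] <- merge_down(above[v], down[kl], app)
      anc_app <- bitwAnd(above[v], app) != 0L
      anc_set <- above[v]
    }
    nadj <- anc_app + (bitwAnd(down[kl], app) != 0L) +
      (bitwAnd(down[kr], app) != 0L)
    if (nadj >= 2L) {
      flag[v] <- TRUE
      s <- bitwAnd(down[v], app)
      if (s == 0L) s <- bitwAnd(bitwOr(down[kl], down[kr]), app)
      if (s == 0L) s <- bitwAnd(anc_set, app)
      up[v] <- s
    } else {
      flag[v] <- FALSE
      up[v] <- INAPP_BIT
    }
  }
  # an applicable region must contain at least one taxon actually observed
  # with an applicable state: flip any connected component of applicable
  # vertices that no unambiguously applicable tip adjoins
  tipm <- rec$tipmask
  anchor_tip <- bitwAnd(tipm, app) != 0L & bitwAnd(tipm, INAPP_BIT) == 0L
  internals <- rec$porder
  visited <- logical(rec$nv)
  for (v0 in internals) {
    if (!flag[v0] || visited[v0]) next
    comp <- integer(0)
    anchored <- FALSE
    stack <- v0
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[v]) next
      visited[v] <- TRUE
      comp <- c(comp, v)
      for (u in c(rec$parent[v], rec$kids[, v])) {
        if (u == 0L) next
        if (u <= rec$ntip) {
          if (anchor_tip[u]) anchored <- TRUE
        } else if (flag[u] && !visited[u]) {
          stack <- c(stack, u)
        }
      }
    }
    if (!anchored) {
      flag[comp] <- FALSE
      up[comp] <- INAPP_BIT
    }
  }
  rec$up <- up
  rec$above <- above
  rec$flag <- flag
  rec$stage <- "up1"
  rec
}

#' Resolve ambiguous tips
#'
#' A tip whose (missing-expanded) set carries both applicable and
#' inapplicable states is made purely applicable if its parent was resolved
#' applicable, and purely inapplicable otherwise.  Tip trackers are set:
#' true iff the tip carries an applicable state.
#'
#' @param rec Record after [first_uppass()].
#' @return The record with `resolved` tip sets and tip trackers.
#' @export
resolve_tips <- function(rec) {
  app <- rec$app
  resolved <- rec$resolved
  for (t in seq_len(rec$ntip)) {
    m <- rec$tipmask[[t]]
    resolved[t] <- if (bitwAnd(m, app) != 0L &&
                       bitwAnd(m, INAPP_BIT) != 0L) {
      if (rec$flag[rec$parent[t]]) bitwAnd(m, app) else INAPP_BIT
    } else {
      m
    }
    rec$tracker[t] <- bitwAnd(resolved[t], app) != 0L
  }
  rec$resolved <- resolved
  rec$stage <- "tips"
  rec
}

#' Second downpass: applicable-state Fitch pass that scores the tree
#'
#' Post-order pass over resolved nodes.  At an applicable node: states
#' shared by the children are kept at no cost; if both children carry
#' applicable states but share none, their applicable union is taken and
#' one step is added; otherwise the node takes whichever child's applicable
#' states exist, and one region is added if both child trackers report an
#' applicable region below.  At an inapplicable node, one region is added
#' under the same tracker condition.  A node's tracker is the OR of its
#' children's.
#'
#' @param rec Record after [resolve_tips()].
#' @return The record with `work`, `steps`, `regions` filled.
#' @export
second_downpass <- function(rec) {
  app <- rec$app
  work <- rec$work
  work[seq_len(rec$ntip)] <- rec$resolved[seq_len(rec$ntip)]
  tracker <- rec$tracker
  steps <- 0L
  regions <- 0L
  for (v in rec$porder) {
    kl <- rec$kids[1L, v]; kr <- rec$kids[2L, v]
    l <- work[kl]; r <- work[kr]
    both_track <- tracker[kl] && tracker[kr]
    if (rec$flag[v]) {
      common_app <- bitwAnd(bitwAnd(l, r), app)
      if (common_app != 0L) {
        work[v] <- common_app
      } else {
        l_app <- bitwAnd(l, app); r_app <- bitwAnd(r, app)
        if (l_app != 0L && r_app != 0L) {
          work[v] <- bitwOr(l_app, r_app)
          steps <- steps + 1L
        } else {
          s <- bitwOr(l_app, r_app)
          if (s == 0L) s <- rec$up[v]
          work[v] <- s
          if (both_track) regions <- regions + 1L
        }
      }
    } else {
      work[v] <- INAPP_BIT
      if (both_track) regions <- regions + 1L
    }
    tracker[v] <- tracker[kl] || tracker[kr]
  }
  rec$work <- work
  rec$tracker <- tracker
  rec$steps <- steps
  rec$regions <- regions
  rec$stage <- "down2"
  rec
}

#' Second uppass: final ancestral state sets
#'
#' Pre-order pass applying the standard Fitch final-state rules restricted
#' to applicable states.  An applicable node whose ancestor is inapplicable
#' (or which is the root) keeps its working set -- it heads an applicable
#' region; when all ancestral states occur in the node's working set, those
#' shared states become final; otherwise missing ancestral states are added
#' (directly when the node was formed by a union, intersected with the
#' children's states when it was formed by an intersection).  Inapplicable
#' nodes stay the inapplicable singleton.  The score is unchanged.
#'
#' @param rec Record after [second_downpass()].
#' @return The record with `final` filled.
#' @export
second_uppass <- function(rec) {
  app <- rec$app
  final <- rec$final
  final[seq_len(rec$ntip)] <- rec$resolved[seq_len(rec$ntip)]
  for (v in rev(rec$porder)) {
    if (!rec$flag[v]) {
      final[v] <- INAPP_BIT
      next
    }
    w <- rec$work[v]
    if (v == rec$root) {
      final[v] <- w
      next
    }
    a <- final[rec$parent[v]]
    if (a == INAPP_BIT) {
      final[v] <- w
      next
    }
    a_app <- bitwAnd(a, app)
    if (bitwAnd(a_app, w) == a_app) {
      final[v] <- a_app
    } else {
      l <- rec$work[rec$kids[1L, v]]
      r <- rec$work[rec$kids[2L, v]]
      if (bitwAnd(bitwAnd(l, r), app) != 0L) {
        final[v] <- bitwOr(w, bitwAnd(a_app, bitwAnd(bitwOr(l, r), app)))
      } else {
        final[v] <- bitwOr(w, a_app)
      }
    }
  }
  rec$final <- final
  rec$stage <- "up2"
  rec
}

# restrict a column to the taxa of a tree (error if a tip is not scored)
column_for_tree <- function(phy, column) {
  idx <- match(phy$tip.label, names(column$masks))
  if (anyNA(idx)) {
    stop("taxon '", phy$tip.label[which(is.na(idx))[1]],
         "' is absent from the character", call. = FALSE)
  }
  column$masks <- column$masks[idx]
  column$missing <- column$missing[idx]
  column
}

#' Score one character on a tree
#'
#' Computes the character's contribution to the tree score: transformation
#' steps plus additional applicable regions.  Characters with fewer than
#' three observed gap-bearing cells are scored by plain Fitch with the gap
#' treated as missing data (the two treatments agree there, and Fitch is
#' cheaper); others run the three scoring passes.  Pass columns with their
#' missing markers intact: expansion happens internally, and missing cells
#' do not count towards the dispatch threshold.
#'
#' @param phy Rooted, strictly binary `phylo`.
#' @param column A [morph_column()].
#' @return An object of class `score_breakdown`: list with `steps`,
#'   `extra_regions`, `total`.
#' @examples
#' phy <- parse_newick("((((A,B),C),(D,E)),((F,G),H));")
#' m <- parse_matrix(c("xread 1 8", "A 1", "B 1", "C 0", "D -", "E -",
#'                     "F 0", "G 0", "H -", ";"), "tnt")
#' score_character(phy, m$columns[[1]])  # 1 step + 1 extra region = 2
#' @export
score_character <- function(phy, column) {
  assert_binary_rooted(phy)
  column <- column_for_tree(phy, column)
  if (length(column$alphabet$applicable) == 0L) {
    return(score_breakdown(0L, 0L))
  }
  # dispatch on observed cells whose set carries the inapplicable state
  # (the exact {-} singletons, plus rare gap-bearing polymorphisms; missing
  # cells do not count, so pass unexpanded columns here)
  gap_bearing <- sum(bitwAnd(column$masks, INAPP_BIT) != 0L &
                       !column$missing)
  if (gap_bearing < 3L) {
    len <- fitch_missing_length(phy, column)
    return(score_breakdown(len, 0L))
  }
  rec <- character_record(phy, expand_missing(column, "all_states"))
  rec <- second_downpass(resolve_tips(first_uppass(first_downpass(rec))))
  score_breakdown(rec$steps, rec$regions)
}

score_breakdown <- function(steps, extra_regions) {
  structure(list(steps = as.integer(steps),
                 extra_regions = as.integer(extra_regions),
                 total = as.integer(steps + extra_regions)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("score ", x$total, " (", x$steps, " steps + ", x$extra_regions,
      " extra regions)\n", sep = "")
  invisible(x)
}

#' Score a whole matrix on a tree
#'
#' Sums independent per-character contributions under one of the three
#' treatments of inapplicable tokens: the inapplicable-aware algorithm
#' (`"inapplicable"`), gap-as-missing Fitch (`"missing"`), or
#' gap-as-extra-state Fitch (`"extra_state"`).
#'
#' @param phy Rooted, strictly binary `phylo`.
#' @param matrix A [morph_matrix()].
#' @param method One of `"inapplicable"`, `"missing"`, `"extra_state"`.
#' @param weights Optional numeric per-character weights (default 1).
#' @return An object of class `parsimony_score`: `total` plus a tibble
#'   `breakdown` (character, steps, extra_regions, total, weight).
#' @export
score_matrix <- function(phy, matrix,
                         method = c("inapplicable", "missing",
                                    "extra_state"),
                         weights = NULL) {
  method <- match.arg(method)
  ncol <- length(matrix$columns)
  if (is.null(weights)) weights <- rep(1, ncol)
  stopifnot(length(weights) == ncol)
  rows <- lapply(seq_len(ncol), function(j) {
    col <- matrix$columns[[j]]
    b <- switch(method,
      inapplicable = score_character(phy, col),
      missing = score_breakdown(
        fitch_missing_length(phy, column_for_tree(phy, col)), 0L),
      extra_state = score_breakdown(
        fitch_extra_state_length(phy, column_for_tree(phy, col)), 0L))
    tibble::tibble(character = j, steps = b$steps,
                   extra_regions = b$extra_regions, total = b$total,
                   weight = weights[j])
  })
  breakdown <- do.call(rbind, rows)
  structure(list(total = sum(breakdown$total * breakdown$weight),
                 breakdown = breakdown, method = method),
            class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat("<parsimony_score> method '", x$method, "', total ", x$total, "\n",
      sep = "")
  print(x$breakdown, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname score_matrix
#' @param x A `parsimony_score`.
#' @param ... Unused.
#' @method tidy parsimony_score
#' @export
tidy.parsimony_score <- function(x, ...) x$breakdown

#' @rdname score_matrix
#' @method glance parsimony_score
#' @export
glance.parsimony_score <- function(x, ...) {
  tibble::tibble(method = x$method, total = x$total,
                 steps = sum(x$breakdown$steps),
                 extra_regions = sum(x$breakdown$extra_regions),
                 n_characters = nrow(x$breakdown))
}

#' Ancestral state reconstruction for one character
#'
#' Runs all four passes and reports the final state set at every vertex:
#' purely applicable sets inside applicable regions, the inapplicable
#' singleton elsewhere.  The score equals [score_character()] -- the fourth
#' pass assigns states only.
#'
#' @param phy Rooted, strictly binary `phylo`.
#' @param column A [morph_column()].
#' @return List with `states` (tibble: node, type, set), `final_masks`
#'   (integer vector over all vertices), and `score` (a `score_breakdown`).
#' @export
ancestral_states <- function(phy, column) {
  assert_binary_rooted(phy)
  column <- column_for_tree(phy, column)
  score <- score_character(phy, column)     # dispatch sees missing markers
  column <- expand_missing(column, "all_states")
  rec <- character_record(phy, column)
  rec <- second_uppass(second_downpass(resolve_tips(first_uppass(
    first_downpass(rec)))))
  sets <- vapply(seq_len(rec$nv), function(v) {
    if (rec$final[v] == INAPP_BIT) column$alphabet$inapplicable
    else mask_to_string(rec$final[v], column$alphabet)
  }, character(1))
  states <- tibble::tibble(
    node = seq_len(rec$nv),
    label = c(phy$tip.label, rep(NA_character_, rec$nv - rec$ntip)),
    type = rep(c("tip", "internal"), c(rec$ntip, rec$nv - rec$ntip)),
    set = sets)
  list(states = states, final_masks = rec$final, score = score,
       record = rec)
}
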