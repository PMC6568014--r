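# The two traditional treatments of inapplicable tokens, both served by
# one plain Fitch downpass engine parameterised by the token mapping, so
# that the three scoring methods differ only in their stated treatment.

# standard Fitch downpass length over integer bit-masks (no empty tips)
fitch_engine_length <- function(rec_phy, tipmasks) {
  phy <- rec_phy
  po <- stats::reorder(phy, "postorder")
  porder <- unique(po$edge[, 1])
  nv <- length(phy$tip.label) + phy$Nnode
  kids <- matrix(0L, 2L, nv)
  for (v in porder) kids[, v] <- phy$edge[phy$edge[, 1] == v, 2]
  s <- integer(nv)
  s[seq_along(tipmasks)] <- tipmasks
  len <- 0L
  for (v in porder) {
    l <- s[kids[1L, v]]; r <- s[kids[2L, v]]
    common <- bitwAnd(l, r)
    if (common != 0L) {
      s[v] <- common
    } else {
      s[v] <- bitwOr(l, r)
      len <- len + 1L
    }
  }
  len
}

fitch_tipmasks <- function(phy, column, treat) {
  idx <- match(phy$tip.label, names(column$masks))
  if (anyNA(idx)) {
    stop("taxon '", phy$tip.label[which(is.na(idx))[1]],
         "' is absent from the character", call. = FALSE)
  }
  column$masks <- column$masks[idx]
  column$missing <- column$missing[idx]
  column <- expand_missing(column, "all_states")
  app <- app_mask(column$alphabet)
  m <- column$masks
  if (treat == "missing") {
    # gap and missing both become "any applicable state"
    m <- bitwAnd(m, app)
    m[m == 0L] <- app
  }
  # extra_state: the inapplicable bit is an ordinary state; the expanded
  # missing cells already span all k + 1 states
  m
}

#' Tree length treating inapplicable tokens as missing data
#'
#' Standard Fitch length after mapping both `-` and `?` to the full set of
#' the character's applicable states (the "missing" approach).
#'
#' @param phy Rooted, strictly binary `phylo`.
#' @param column A [morph_column()].
#' @return Integer length (number of steps).
#' @export
fitch_missing_length <- function(phy, column) {
  assert_binary_rooted(phy)
  if (length(column$alphabet$applicable) == 0L) return(0L)
  fitch_engine_length(phy, fitch_tipmasks(phy, column, "missing"))
}

#' Tree length treating inapplicability as an extra state
#'
#' Standard Fitch length over the augmented alphabet in which `-` is an
#' ordinary (k+1)-th state and `?` spans all k + 1 states (the "extra
#' state" approach).
#'
#' @inheritParams fitch_missing_length
#' @return Integer length (number of steps).
#' @export
fitch_extra_state_length <- function(phy, column) {
  assert_binary_rooted(phy)
  if (length(column$alphabet$applicable) == 0L &&
      all(column$masks == INAPP_BIT | column$missing)) {
    return(0L)
  }
  fitch_engine_length(phy, fitch_tipmasks(phy, column, "extra_state"))
}
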