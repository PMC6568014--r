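#' Worked example: a character split into two applicable regions
#'
#' A 12-taxon pectinate tree carrying one reductively coded character whose
#' principal structure is present in two separate regions of the tree.
#' Inside the first region a transformation from state 1 to state 0 adds
#' one step to tree length; the second region exhibits an independent
#' occurrence of state 0 -- a case of homoplasy -- and adds one additional
#' applicable region.  The character's contribution to the tree score is
#' therefore 2 (one step + one extra region).
#'
#' @return List with `tree` (rooted binary `phylo`), `matrix` (a
#'   [morph_matrix()] with the single character), and `expected_score`
#'   (integer 2).
#' @examples
#' ex <- two_region_example()
#' score_character(ex$tree, ex$matrix$columns[[1]])
#' @export
two_region_example <- function() {
  nwk <- "(((((((((((t1,t2),t3),t4),t5),t6),t7),t8),t9),t10),t11),t12);"
  states <- c("1", "1", "0", "-", "-", "-", "0", "0", "-", "-", "-", "-")
  taxa <- paste0("t", 1:12)
  rows <- paste(taxa, states)
  list(tree = parse_newick(nwk),
       matrix = parse_matrix(c("xread 1 12", rows, ";"), "tnt"),
       expected_score = 2L)
}
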