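# shared fixture builders; everything is generated in code

col_from_states <- function(states, taxa = paste0("t", seq_along(states))) {
  txt <- c(paste("xread 1", length(states)), paste(taxa, states), ";")
  parse_matrix(txt, "tnt")$columns[[1]]
}

mat_from_rows <- function(rows, taxa = paste0("t", seq_along(rows))) {
  nchar_mat <- nchar(gsub("\\([^)]*\\)", "x", rows[1]))
  txt <- c(paste("xread", nchar_mat, length(rows)), paste(taxa, rows), ";")
  parse_matrix(txt, "tnt")
}

# run the full scoring passes without the small-gap-count dispatch
full_pass_total <- function(phy, col) {
  rec <- second_downpass(resolve_tips(first_uppass(first_downpass(
    character_record(phy, expand_missing(col, "all_states"))))))
  rec$steps + rec$regions
}

# independent textbook Fitch length via phangorn (single-state tips only)
phangorn_fitch_length <- function(phy, states, levels) {
  m <- matrix(states, ncol = 1,
              dimnames = list(names(states), NULL))
  d <- phangorn::phyDat(m, type = "USER", levels = levels)
  as.integer(phangorn::fitch(phy, d))
}

# independent textbook Fitch down+up passes over bit-masks; returns final
# state sets (used to check the fourth pass on gap-free characters)
textbook_fitch_finals <- function(phy, tipmasks) {
  nt <- length(phy$tip.label)
  nv <- nt + phy$Nnode
  po <- unique(stats::reorder(phy, "postorder")$edge[, 1])
  kids <- matrix(0L, 2, nv)
  for (v in po) kids[, v] <- phy$edge[phy$edge[, 1] == v, 2]
  parent <- integer(nv)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  s <- integer(nv)
  s[1:nt] <- tipmasks
  for (v in po) {
    l <- s[kids[1, v]]; r <- s[kids[2, v]]
    cm <- bitwAnd(l, r)
    s[v] <- if (cm != 0L) cm else bitwOr(l, r)
  }
  f <- s
  for (v in rev(po)) {
    if (v == nt + 1L) next
    a <- f[parent[v]]
    if (bitwAnd(s[v], a) == a) { f[v] <- a; next }
    l <- s[kids[1, v]]; r <- s[kids[2, v]]
    f[v] <- if (bitwAnd(l, r) != 0L) {
      bitwOr(s[v], bitwAnd(a, bitwOr(l, r)))
    } else {
      bitwOr(s[v], a)
    }
  }
  f
}
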