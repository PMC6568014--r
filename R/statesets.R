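# State sets are integer bit-masks: bit 0 (value 1L) is the inapplicable
# state, bit i (i >= 1) is the i-th applicable symbol of the column's
# alphabet.  R integers are 32-bit signed, so a column may carry at most
# 30 applicable states -- ample for published morphological matrices.

INAPP_BIT <- 1L
MAX_STATES <- 30L

#' Character alphabet
#'
#' The symbol table of one character: an ordered set of single-character
#' applicable symbols, plus the tokens used for inapplicability (the "gap",
#' by default `-`) and missing data (by default `?`).
#'
#' @param applicable Character vector of single-character applicable symbols.
#' @param inapplicable Single-character inapplicable (gap) token.
#' @param missing Single-character missing-data token.
#' @return An object of class `morph_alphabet`.
#' @examples
#' morph_alphabet(c("0", "1", "2"))
#' @export
morph_alphabet <- function(applicable, inapplicable = "-", missing = "?") {
  applicable <- as.character(applicable)
  if (any(nchar(applicable) != 1L) || nchar(inapplicable) != 1L ||
      nchar(missing) != 1L) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (anyDuplicated(applicable)) {
    stop("duplicated applicable symbols", call. = FALSE)
  }
  if (length(applicable) > MAX_STATES) {
    stop("at most ", MAX_STATES, " applicable states are supported",
         call. = FALSE)
  }
  syms <- c(applicable, inapplicable, missing)
  if (anyDuplicated(syms)) {
    stop("applicable, inapplicable and missing symbols must be distinct",
         call. = FALSE)
  }
  structure(list(applicable = applicable, inapplicable = inapplicable,
                 missing = missing),
            class = "morph_alphabet")
}

#' @export
print.morph_alphabet <- function(x, ...) {
  cat("<morph_alphabet> applicable: {",
      paste(x$applicable, collapse = " "), "}  inapplicable: ",
      x$inapplicable, "  missing: ", x$missing, "\n", sep = "")
  invisible(x)
}

# mask with every applicable bit of `alphabet` set
app_mask <- function(alphabet) {
  k <- length(alphabet$applicable)
  if (k == 0L) return(0L)
  as.integer(bitwShiftL(1L, k + 1L) - 2L)
}

full_mask <- function(alphabet) bitwOr(app_mask(alphabet), INAPP_BIT)

# mask for a vector of observed tokens (symbols, "-" allowed; not "?")
mask_from_tokens <- function(tokens, alphabet) {
  m <- 0L
  for (tok in tokens) {
    if (tok == alphabet$inapplicable) {
      m <- bitwOr(m, INAPP_BIT)
    } else {
      i <- match(tok, alphabet$applicable)
      if (is.na(i)) return(NA_integer_)
      m <- bitwOr(m, bitwShiftL(1L, i))
    }
  }
  m
}

# human-readable rendering of a mask, e.g. "{0,1,-}"
mask_to_string <- function(mask, alphabet) {
  toks <- alphabet$applicable[
    bitwAnd(mask, bitwShiftL(1L, seq_along(alphabet$applicable))) != 0L]
  if (bitwAnd(mask, INAPP_BIT) != 0L) toks <- c(toks, alphabet$inapplicable)
  paste0("{", paste(toks, collapse = ","), "}")
}

has_applicable <- function(mask, alphabet) {
  bitwAnd(mask, app_mask(alphabet)) != 0L
}

has_inapplicable <- function(mask) bitwAnd(mask, INAPP_BIT) != 0L

#' Single character column
#'
#' One transformation series: a state set per taxon plus the column's
#' alphabet.  Cells recorded as missing (`?`) carry an empty mask and a
#' `missing` flag until [expand_missing()] is applied.
#'
#' @param masks Named integer vector of state-set bit-masks (one per taxon).
#' @param alphabet A [morph_alphabet()].
#' @param missing Logical vector marking unexpanded missing cells.
#' @param label Optional character label.
#' @return An object of class `morph_column`.
#' @export
morph_column <- function(masks, alphabet, missing = rep(FALSE, length(masks)),
                         label = NULL) {
  stopifnot(is.integer(masks), !is.null(names(masks)),
            length(missing) == length(masks))
  if (any(masks == 0L & !missing)) {
    stop("empty state set for non-missing cell", call. = FALSE)
  }
  structure(list(masks = masks, alphabet = alphabet, missing = missing,
                 label = label),
            class = "morph_column")
}

#' @export
print.morph_column <- function(x, ...) {
  cells <- vapply(seq_along(x$masks), function(i) {
    if (x$missing[i]) x$alphabet$missing else
      mask_to_string(x$masks[i], x$alphabet)
  }, character(1))
  cat("<morph_column", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      "> ", length(x$masks), " taxa, states {",
      paste(x$alphabet$applicable, collapse = ""), "}\n", sep = "")
  print(stats::setNames(cells, names(x$masks)))
  invisible(x)
}

#' Count of purely inapplicable cells
#'
#' Number of taxa whose state set is exactly the inapplicable singleton.
#' Characters with fewer than three such cells do not need the
#' inapplicable-aware algorithm and are scored by plain Fitch with the gap
#' treated as missing.
#'
#' @param column A [morph_column()].
#' @return Integer count.
#' @export
n_inapplicable <- function(column) {
  sum(column$masks == INAPP_BIT & !column$missing)
}

#' Morphological character matrix
#'
#' An ordered taxon list plus a list of [morph_column()]s that all share it.
#'
#' @param taxa Character vector of unique taxon labels.
#' @param columns List of `morph_column` objects.
#' @return An object of class `morph_matrix`.
#' @export
morph_matrix <- function(taxa, columns) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique", call. = FALSE)
  for (col in columns) {
    if (!identical(names(col$masks), taxa)) {
      stop("all columns must share the matrix taxon list", call. = FALSE)
    }
  }
  structure(list(taxa = taxa, columns = columns), class = "morph_matrix")
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("<morph_matrix> ", length(x$taxa), " taxa x ", length(x$columns),
      " characters\n", sep = "")
  invisible(x)
}

#' @export
dim.morph_matrix <- function(x) c(length(x$taxa), length(x$columns))

#' Convert a matrix to a tibble of state strings
#'
#' One row per taxon, one column per character; cells hold the state tokens
#' (`"01"` for a polymorphic cell, the gap or missing token where relevant).
#'
#' @param x A [morph_matrix()].
#' @param ... Unused.
#' @return A tibble with a `taxon` column plus one column per character.
#' @importFrom tibble as_tibble
#' @method as_tibble morph_matrix
#' @export
as_tibble.morph_matrix <- function(x, ...) {
  cols <- lapply(seq_along(x$columns), function(j) {
    col <- x$columns[[j]]
    vapply(seq_along(col$masks), function(i) cell_token(col, i), character(1))
  })
  names(cols) <- vapply(seq_along(x$columns), function(j) {
    lbl <- x$columns[[j]]$label
    if (is.null(lbl)) paste0("char", j) else lbl
  }, character(1))
  tibble::as_tibble(c(list(taxon = x$taxa), cols))
}

# ---- parsing -------------------------------------------------------------

# split one row string into cell tokens, honouring "(..)" and "{..}" groups
tokenize_row <- function(row, taxon) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  chars <- chars[!chars %in% c(" ", "\t")]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        grp <- c(grp, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) {
        stop("unterminated state group in row for taxon '", taxon, "'",
             call. = FALSE)
      }
      if (length(grp) == 0L) {
        stop("empty state group in row for taxon '", taxon, "'",
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- grp
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  out
}

# build morph_column list from a taxon -> token-list mapping.
# Per-column alphabets are the symbols observed in that column (ordered by
# `symbol_order` when declared, else lexicographically).
columns_from_cells <- function(taxa, cells, missing_sym, gap_sym,
                               symbol_order = NULL, labels = NULL) {
  nchar_mat <- length(cells[[1]])
  for (t in taxa) {
    if (length(cells[[t]]) != nchar_mat) {
      stop("row length mismatch for taxon '", t, "': expected ", nchar_mat,
           ", got ", length(cells[[t]]), call. = FALSE)
    }
  }
  lapply(seq_len(nchar_mat), function(j) {
    toks <- unique(unlist(lapply(taxa, function(t) cells[[t]][[j]])))
    app <- setdiff(toks, c(missing_sym, gap_sym))
    app <- if (is.null(symbol_order)) sort(app) else
      symbol_order[symbol_order %in% app]
    alph <- morph_alphabet(if (length(app)) app else character(0),
                           inapplicable = gap_sym, missing = missing_sym)
    miss <- logical(length(taxa))
    masks <- integer(length(taxa))
    for (i in seq_along(taxa)) {
      cell <- cells[[taxa[i]]][[j]]
      if (length(cell) == 1L && cell == missing_sym) {
        miss[i] <- TRUE
      } else {
        m <- mask_from_tokens(cell, alph)
        if (is.na(m)) {
          stop("undeclared symbol in character ", j, ", taxon '", taxa[i],
               "'", call. = FALSE)
        }
        masks[i] <- m
      }
    }
    names(masks) <- taxa
    morph_column(masks, alph, miss,
                 label = if (!is.null(labels)) labels[j] else NULL)
  })
}

#' Parse a character matrix
#'
#' Reads a discrete character matrix from NEXUS (`DATA`/`CHARACTERS` block;
#' `SYMBOLS`, `MISSING` and `GAP` honoured) or TNT (`xread`) text.
#' Parenthesised `(01)` and braced `{01}` groups are both read as state
#' sets; the missing token is kept as a pending marker until
#' [expand_missing()].  Each column's applicable alphabet is the set of
#' symbols observed in that column, so that missing-data expansion uses all
#' possible states of that character.
#'
#' @param text Character scalar (or vector of lines) of matrix text.
#' @param dialect `"nexus"` or `"tnt"`.
#' @return A [morph_matrix()].
#' @examples
#' nex <- c("#NEXUS", "BEGIN DATA;",
#'          "DIMENSIONS NTAX=3 NCHAR=2;",
#'          "FORMAT SYMBOLS=\"01\" MISSING=? GAP=-;",
#'          "MATRIX", "A 01", "B 1-", "C ?0", ";", "END;")
#' parse_matrix(nex, "nexus")
#' @export
parse_matrix <- function(text, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  lines <- sub("\\[[^]]*\\]", "", lines)   # strip single-line comments
  if (dialect == "nexus") parse_nexus(lines) else parse_tnt(lines)
}

parse_nexus <- function(lines) {
  up <- toupper(lines)
  beg <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (length(beg) == 0L) stop("no DATA or CHARACTERS block found",
                              call. = FALSE)
  blk_end <- grep("^\\s*END\\s*;", up)
  blk_end <- blk_end[blk_end > beg[1]][1]
  if (is.na(blk_end)) stop("unterminated NEXUS block", call. = FALSE)
  blk <- lines[(beg[1] + 1L):(blk_end - 1L)]
  ublk <- toupper(blk)

  missing_sym <- "?"; gap_sym <- "-"; symbols <- NULL
  ntax <- nchar_decl <- NA_integer_
  dim_line <- grep("^\\s*DIMENSIONS", ublk, value = TRUE)
  if (length(dim_line)) {
    m <- regmatches(dim_line[1],
                    regexec("NTAX\\s*=\\s*([0-9]+)", toupper(dim_line[1])))[[1]]
    if (length(m) == 2L) ntax <- as.integer(m[2])
    m <- regmatches(dim_line[1],
                    regexec("NCHAR\\s*=\\s*([0-9]+)", toupper(dim_line[1])))[[1]]
    if (length(m) == 2L) nchar_decl <- as.integer(m[2])
  }
  fmt_i <- grep("^\\s*FORMAT", ublk)
  if (length(fmt_i)) {
    fmt <- blk[fmt_i[1]]
    m <- regmatches(fmt, regexec("SYMBOLS\\s*=\\s*\"([^\"]*)\"", fmt,
                                 ignore.case = TRUE))[[1]]
    if (length(m) == 2L) {
      symbols <- strsplit(gsub(" ", "", m[2]), "")[[1]]
    }
    m <- regmatches(fmt, regexec("MISSING\\s*=\\s*(\\S)", fmt,
                                 ignore.case = TRUE))[[1]]
    if (length(m) == 2L) missing_sym <- m[2]
    m <- regmatches(fmt, regexec("GAP\\s*=\\s*(\\S)", fmt,
                                 ignore.case = TRUE))[[1]]
    if (length(m) == 2L) gap_sym <- m[2]
  }

  mat_i <- grep("^\\s*MATRIX", ublk)
  if (length(mat_i) == 0L) stop("no MATRIX section found", call. = FALSE)
  rows <- blk[(mat_i[1] + 1L):length(blk)]
  semi <- grep(";", rows)
  if (length(semi)) {
    rows[semi[1]] <- sub(";.*$", "", rows[semi[1]])
    rows <- rows[seq_len(semi[1])]
  }
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  parse_matrix_rows(rows, missing_sym, gap_sym, symbols, ntax, nchar_decl)
}

parse_tnt <- function(lines) {
  up <- toupper(lines)
  x_i <- grep("^\\s*XREAD", up)
  if (length(x_i) == 0L) stop("no xread block found", call. = FALSE)
  rest <- lines[x_i[1]:length(lines)]
  rest[1] <- sub("^\\s*[Xx][Rr][Ee][Aa][Dd]", "", rest[1])
  txt <- paste(rest, collapse = "\n")
  txt <- gsub("'[^']*'", "", txt)               # quoted title
  semi <- regexpr(";", txt, fixed = TRUE)
  if (semi > 0L) txt <- substr(txt, 1L, semi - 1L)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  if (length(toks) < 2L || is.na(suppressWarnings(as.integer(toks[1])))) {
    stop("malformed xread header (expected 'nchar ntax')", call. = FALSE)
  }
  nchar_decl <- as.integer(toks[1]); ntax <- as.integer(toks[2])
  rows_toks <- toks[-(1:2)]
  if (length(rows_toks) %% 2L != 0L) {
    stop("malformed xread rows", call. = FALSE)
  }
  rows <- paste(rows_toks[seq(1, length(rows_toks), by = 2)],
                rows_toks[seq(2, length(rows_toks), by = 2)])
  parse_matrix_rows(rows, "?", "-", NULL, ntax, nchar_decl)
}

parse_matrix_rows <- function(rows, missing_sym, gap_sym, symbols,
                              ntax = NA, nchar_decl = NA) {
  taxa <- character(0)
  cells <- list()
  for (row in rows) {
    sp <- regmatches(row, regexpr("\\s", row))
    if (length(sp) == 0L) stop("matrix row without states: '", row, "'",
                               call. = FALSE)
    pos <- regexpr("\\s", row)
    taxon <- substr(row, 1L, pos - 1L)
    states <- trimws(substr(row, pos + 1L, nchar(row)))
    if (taxon %in% taxa) stop("duplicated taxon '", taxon, "'",
                              call. = FALSE)
    taxa <- c(taxa, taxon)
    cells[[taxon]] <- tokenize_row(states, taxon)
  }
  if (!is.na(ntax) && length(taxa) != ntax) {
    stop("declared NTAX=", ntax, " but found ", length(taxa), " rows",
         call. = FALSE)
  }
  if (!is.na(nchar_decl)) {
    for (t in taxa) {
      if (length(cells[[t]]) != nchar_decl) {
        stop("taxon '", t, "' has ", length(cells[[t]]),
             " characters, expected ", nchar_decl, call. = FALSE)
      }
    }
  }
  if (!is.null(symbols)) {
    seen <- setdiff(unique(unlist(cells)), c(missing_sym, gap_sym))
    bad <- setdiff(seen, symbols)
    if (length(bad)) {
      stop("symbol(s) not declared in SYMBOLS: ",
           paste(bad, collapse = " "), call. = FALSE)
    }
  }
  cols <- columns_from_cells(taxa, cells, missing_sym, gap_sym,
                             symbol_order = symbols)
  morph_matrix(taxa, cols)
}

# ---- serialization -------------------------------------------------------

cell_token <- function(col, i) {
  if (col$missing[i]) return(col$alphabet$missing)
  m <- col$masks[i]
  toks <- col$alphabet$applicable[
    bitwAnd(m, bitwShiftL(1L, seq_along(col$alphabet$applicable))) != 0L]
  if (has_inapplicable(m)) toks <- c(toks, col$alphabet$inapplicable)
  if (length(toks) == 1L) toks else paste0("(", paste(toks, collapse = ""),
                                           ")")
}

matrix_row_strings <- function(x) {
  vapply(seq_along(x$taxa), function(i) {
    paste(vapply(x$columns, function(col) cell_token(col, i), character(1)),
          collapse = "")
  }, character(1))
}

#' Serialize a character matrix
#'
#' Writes a [morph_matrix()] back to NEXUS or TNT text.  Round-tripping
#' through [parse_matrix()] preserves every state set.
#'
#' @param x A [morph_matrix()].
#' @param dialect `"nexus"` or `"tnt"`.
#' @param file Optional path; when `NULL` the text is returned.
#' @return Character vector of lines (invisibly, when `file` is given).
#' @export
write_matrix <- function(x, dialect = c("nexus", "tnt"), file = NULL) {
  dialect <- match.arg(dialect)
  symbols <- sort(unique(unlist(lapply(x$columns,
                                       function(c) c$alphabet$applicable))))
  rows <- matrix_row_strings(x)
  name_w <- max(nchar(x$taxa))
  padded <- formatC(x$taxa, width = -(name_w + 2L))
  lines <- if (dialect == "nexus") {
    c("#NEXUS",
      "BEGIN DATA;",
      paste0("DIMENSIONS NTAX=", length(x$taxa), " NCHAR=",
             length(x$columns), ";"),
      paste0("FORMAT SYMBOLS=\"", paste(symbols, collapse = ""),
             "\" MISSING=? GAP=-;"),
      "MATRIX",
      paste0(padded, rows),
      ";",
      "END;")
  } else {
    c(paste0("xread ", length(x$columns), " ", length(x$taxa)),
      paste0(padded, rows),
      ";")
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

# ---- policies ------------------------------------------------------------

#' Expand missing cells into explicit state sets
#'
#' Replaces every missing-data marker by the polymorphism of all possible
#' states of the character: all applicable states plus the inapplicable
#' state under `"all_states"` (the standard treatment), or the applicable
#' states only under `"applicable_only"` ("unknown, but from the applicable
#' set").  Idempotent.
#'
#' @param column A [morph_column()] or [morph_matrix()].
#' @param policy `"all_states"` or `"applicable_only"`.
#' @return Object of the same class with no missing markers left.
#' @export
expand_missing <- function(column, policy = c("all_states",
                                              "applicable_only")) {
  policy <- match.arg(policy)
  if (inherits(column, "morph_matrix")) {
    column$columns <- lapply(column$columns, expand_missing, policy = policy)
    return(column)
  }
  fill <- if (policy == "all_states") full_mask(column$alphabet)
          else app_mask(column$alphabet)
  if (fill == 0L) fill <- full_mask(column$alphabet)  # all-gap column
  column$masks[column$missing] <- fill
  column$missing[] <- FALSE
  column
}

#' Recode a neomorphic character in additive-binary form
#'
#' Replaces every purely inapplicable cell of a presence/absence
#' (neomorphic) dependent character by the presumed nonderived condition,
#' the additive binary coding: absence of the principal structure is scored
#' as absence of the dependent one.
#'
#' @param column A [morph_column()].
#' @param nonderived_symbol Applicable symbol of the nonderived condition.
#' @return Recoded `morph_column` with no purely inapplicable cells.
#' @examples
#' # "Tail eyespot" scored "-" where the tail is absent becomes "0"
#' @export
recode_neomorphic <- function(column, nonderived_symbol) {
  i <- match(nonderived_symbol, column$alphabet$applicable)
  if (is.na(i)) {
    stop("nonderived symbol '", nonderived_symbol,
         "' is not an applicable symbol of this character", call. = FALSE)
  }
  bit <- bitwShiftL(1L, i)
  inapp_only <- column$masks == INAPP_BIT & !column$missing
  column$masks[inapp_only] <- bit
  column
}
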