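test_that("minimal matrices parse to the expected masks in both dialects", {
  nex <- c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=1;",
           "FORMAT SYMBOLS=\"01\" MISSING=? GAP=-;",
           "MATRIX", "A 0", "B 1", ";", "END;")
  tnt <- c("xread 1 2", "A 0", "B 1", ";")
  for (m in list(parse_matrix(nex, "nexus"), parse_matrix(tnt, "tnt"))) {
    expect_equal(dim(m), c(2L, 1L))
    expect_equal(unname(m$columns[[1]]$masks), c(2L, 4L))  # {0}, {1}
  }
})

test_that("a reductively coded dependent character row parses faithfully", {
  # tail colour: inapplicable where the tail is absent, ? where unknown
  col <- col_from_states(c("-", "-", "-", "0", "0", "1", "2", "?"))
  expect_equal(col$alphabet$applicable, c("0", "1", "2"))
  expect_equal(unname(col$masks), c(1L, 1L, 1L, 2L, 2L, 4L, 8L, 0L))
  expect_equal(col$missing, c(rep(FALSE, 7), TRUE))
  expect_equal(n_inapplicable(col), 3L)
})

test_that("polymorphisms and ambiguity groups are state sets", {
  col <- col_from_states(c("(01)", "0", "1", "{01}"))
  expect_equal(unname(col$masks), c(6L, 2L, 4L, 6L))
  col2 <- col_from_states(c("(0-)", "0", "1", "-"))
  expect_equal(unname(col2$masks)[1], 3L)        # {0,-}
})

test_that("parse errors name the offender", {
  nex <- c("#NEXUS", "BEGIN DATA;", "FORMAT SYMBOLS=\"01\";",
           "MATRIX", "A 02", "B 11", ";", "END;")
  expect_error(parse_matrix(nex, "nexus"), "not declared")
  expect_error(parse_matrix(c("xread 2 2", "A 01", "B 0", ";"), "tnt"),
               "t.*2|expected", ignore.case = TRUE)
  expect_error(parse_matrix(c("xread 1 2", "A 0", "A 1", ";"), "tnt"),
               "duplicated taxon")
})

test_that("NEXUS MISSING and GAP declarations are honoured", {
  nex <- c("#NEXUS", "BEGIN DATA;",
           "FORMAT SYMBOLS=\"01\" MISSING=* GAP=#;",
           "MATRIX", "A 0#", "B *1", ";", "END;")
  m <- parse_matrix(nex, "nexus")
  expect_equal(unname(m$columns[[2]]$masks[1]), 1L)   # gap
  expect_true(m$columns[[1]]$missing[2])
})

test_that("missing expansion follows the declared policy and is idempotent", {
  col <- col_from_states(c("?", "0", "1", "-"))
  all_states <- expand_missing(col, "all_states")
  expect_equal(unname(all_states$masks[1]), 7L)       # {0,1,-}
  app_only <- expand_missing(col, "applicable_only")
  expect_equal(unname(app_only$masks[1]), 6L)         # {0,1}
  expect_false(any(all_states$missing))
  expect_identical(expand_missing(all_states, "all_states"), all_states)
  # a column without ? is untouched
  col2 <- col_from_states(c("0", "1"))
  expect_identical(expand_missing(col2), col2)
})

test_that("neomorphic recoding produces additive binary coding", {
  # tail eyespot, reductive -> additive binary (nonderived condition "0")
  col <- col_from_states(c("-", "-", "-", "1", "0", "1", "0", "?"))
  rec <- recode_neomorphic(col, "0")
  expect_equal(unname(rec$masks), c(2L, 2L, 2L, 4L, 2L, 4L, 2L, 0L))
  expect_equal(n_inapplicable(rec), 0L)
  # no-op without inapplicable cells
  plain <- col_from_states(c("0", "1", "0"))
  expect_identical(recode_neomorphic(plain, "0"), plain)
  # all-inapplicable column becomes constant
  allgap <- col_from_states(c("-", "-", "-", "0"))
  expect_true(all(recode_neomorphic(allgap, "0")$masks == 2L))
  expect_error(recode_neomorphic(plain, "9"), "not an applicable symbol")
})

test_that("matrices round-trip through both serializations", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    taxa <- paste0("t", 1:n)
    rows <- replicate(n, paste(sample(c("0", "1", "2", "-", "?", "(01)"),
                                      4, replace = TRUE), collapse = ""))
    m <- mat_from_rows(rows, taxa)
    for (dialect in c("nexus", "tnt")) {
      m2 <- parse_matrix(write_matrix(m, dialect), dialect)
      expect_equal(lapply(m2$columns, `[[`, "masks"),
                   lapply(m$columns, `[[`, "masks"))
      expect_equal(lapply(m2$columns, `[[`, "missing"),
                   lapply(m$columns, `[[`, "missing"))
    }
  }
})

test_that("as_tibble renders taxa by characters with original tokens", {
  m <- mat_from_rows(c("0-", "1?", "(01)0"), c("a", "b", "c"))
  tb <- tibble::as_tibble(m)
  expect_equal(tb$taxon, c("a", "b", "c"))
  expect_equal(tb$char1, c("0", "1", "(01)"))
  expect_equal(tb$char2, c("-", "?", "0"))
})
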