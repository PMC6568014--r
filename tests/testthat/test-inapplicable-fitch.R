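# The four passes on single characters with inapplicable states.
# Mask convention in fixtures: bit 0 (value 1) = "-", bit i = i-th symbol.

test_that("first downpass combines child sets by the three node rules", {
  merge_down <- inappfitch:::merge_down
  app <- 6L                                   # two-symbol alphabet {0,1}
  expect_equal(merge_down(5L, 2L, app), 6L)   # {1,-} + {0}  -> {0,1}
  expect_equal(merge_down(1L, 3L, app), 1L)   # {-} + {0,-}  -> {-}
  expect_equal(merge_down(1L, 4L, app), 5L)   # {-} + {1}    -> {1,-}
  expect_equal(merge_down(3L, 5L, app), 7L)   # {0,-}+{1,-}  -> {0,1,-}
  expect_equal(merge_down(2L, 6L, app), 2L)   # {0} + {0,1}  -> {0} (Fitch)
  # total and nonempty over every pair of nonempty sets
  for (l in 1:7) for (r in 1:7) {
    expect_gt(merge_down(l, r, app), 0L)
  }
})

test_that("first uppass resolves applicability from the incident branches", {
  # node with preliminary {0,-}: applicable ancestor side and one
  # applicable child -> applicable, keeping the applicable part
  phy <- parse_newick("((A,B),(C,D));")
  rec <- first_uppass(first_downpass(character_record(
    phy, col_from_states(c("0", "-", "0", "0"), LETTERS[1:4]))))
  n_ab <- 6L                                   # cherry (A,B), prelim {0,-}
  expect_equal(rec$down[n_ab], 3L)
  expect_true(rec$flag[n_ab])
  expect_equal(rec$up[n_ab], 2L)               # {0}
  # node with preliminary {-} between gap tips stays inapplicable
  rec2 <- first_uppass(first_downpass(character_record(
    phy, col_from_states(c("-", "-", "-", "0"), LETTERS[1:4]))))
  expect_false(rec2$flag[6L])                  # cherry (A,B) = {-}
  expect_equal(rec2$up[6L], 1L)
  # ambiguous root with applicables on both sides resolves applicable
  rec3 <- first_uppass(first_downpass(character_record(
    phy, col_from_states(c("0", "-", "1", "-"), LETTERS[1:4]))))
  expect_true(rec3$flag[5L])
  expect_equal(rec3$up[5L], 6L)                # {0,1}
})

test_that("ambiguous tips resolve to their parent's applicability", {
  phy <- parse_newick("((A,B),(C,D));")
  # B is missing (expands to {0,1,-}); its parent is applicable
  rec <- resolve_tips(first_uppass(first_downpass(character_record(
    phy, expand_missing(col_from_states(c("0", "?", "1", "0"),
                                        LETTERS[1:4]))))))
  expect_equal(rec$resolved[2L], 6L)           # {0,1}
  # same tip under an inapplicable parent becomes the gap singleton
  phy8 <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  rec2 <- resolve_tips(first_uppass(first_downpass(character_record(
    phy8, expand_missing(col_from_states(
      c("-", "?", "-", "-", "-", "-", "0", "0"), LETTERS[1:8]))))))
  expect_equal(rec2$resolved[2L], 1L)          # {-}
  # unambiguous tips are unchanged
  expect_equal(rec$resolved[1L], 2L)
})

test_that("second downpass counts steps and extra regions", {
  phy <- parse_newick("((A,B),(C,D));")
  # plain Fitch intersection and union cases
  b <- score_character(phy, col_from_states(c("0", "1", "0", "1"),
                                            LETTERS[1:4]))
  expect_equal(unclass(b)[c("steps", "extra_regions", "total")],
               list(steps = 2L, extra_regions = 0L, total = 2L))
  # all-gap character costs nothing
  expect_equal(score_character(phy, col_from_states(rep("-", 4),
                                                    LETTERS[1:4]))$total, 0L)
  # two single-tip regions joined across inapplicable interior: one region
  phy8 <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  b8 <- score_character(phy8, col_from_states(
    c("0", "-", "-", "-", "-", "-", "0", "-"), LETTERS[1:8]))
  expect_equal(b8$steps, 0L)
  expect_equal(b8$extra_regions, 1L)
  expect_equal(b8$total, 1L)
})

test_that("the two-region worked example scores one step plus one region", {
  ex <- two_region_example()
  b <- score_character(ex$tree, ex$matrix$columns[[1]])
  expect_equal(b$steps, 1L)
  expect_equal(b$extra_regions, 1L)
  expect_equal(b$total, ex$expected_score)
})

test_that("an invariant dependent character in forced-apart regions still
           contributes to the score", {
  phy8 <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  col <- col_from_states(c("0", "-", "-", "-", "-", "-", "0", "-"),
                         LETTERS[1:8])
  expect_gte(score_character(phy8, col)$total, 1L)
})

test_that("matrix scores are sums of independent character scores", {
  phy <- parse_newick("(((((((t1,t2),t3),t4),t5),t6),t7),t8);")
  m <- mat_from_rows(c("0100", "0110", "0101", "1-0?", "1-01", "1-10",
                       "1-1-", "?-0-"))
  ps <- score_matrix(phy, m, "inapplicable")
  per <- vapply(m$columns, function(c) score_character(phy, c)$total,
                integer(1))
  expect_equal(ps$total, sum(per))
  expect_equal(ps$breakdown$total, per)
  # single character equals score_character; duplication doubles
  m1 <- morph_matrix(m$taxa, m$columns[1])
  expect_equal(score_matrix(phy, m1)$total, per[1])
  m2 <- morph_matrix(m$taxa, m$columns[c(1, 1)])
  expect_equal(score_matrix(phy, m2)$total, 2 * per[1])
  # tidy/glance accessors
  expect_s3_class(tidy(ps), "tbl_df")
  expect_equal(glance(ps)$total, ps$total)
})

test_that("ancestral reconstruction matches textbook Fitch when no gaps", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    taxa <- paste0("t", 1:n)
    phy <- random_addition_tree(taxa)
    col <- col_from_states(sample(c("0", "1", "2"), n, replace = TRUE),
                           taxa)
    as <- ancestral_states(phy, col)
    rec <- character_record(phy, col)
    expect_identical(as$final_masks,
                     textbook_fitch_finals(phy, rec$tipmask))
  }
})

test_that("the fourth pass assigns states but never changes the score", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    taxa <- paste0("t", 1:n)
    phy <- random_addition_tree(taxa)
    col <- col_from_states(sample(c("0", "1", "-", "?"), n, replace = TRUE,
                                  prob = c(.3, .3, .3, .1)), taxa)
    if (!any(grepl("[01]", sapply(seq_len(n), function(i)
      inappfitch:::cell_token(col, i))))) next
    as <- ancestral_states(phy, col)
    expect_equal(as$score$total, score_character(phy, col)$total)
    # every vertex is purely applicable or the gap singleton
    app <- inappfitch:::app_mask(col$alphabet)
    ok <- as$final_masks == 1L | bitwAnd(as$final_masks, 1L) == 0L
    expect_true(all(ok[(n + 1):(2 * n - 1)]))
  }
})

test_that("all-gap characters reconstruct every vertex as inapplicable", {
  phy <- parse_newick("((A,B),(C,D));")
  as <- ancestral_states(phy, col_from_states(rep("-", 4), LETTERS[1:4]))
  expect_true(all(as$final_masks == 1L))
  expect_equal(as$score$total, 0L)
})

test_that("scoring validates its inputs", {
  phy <- parse_newick("((A,B),(C,D));")
  col <- col_from_states(c("0", "1", "0"), c("A", "B", "C"))
  expect_error(score_character(phy, col), "absent from the character")
  tri <- parse_newick("(A,B,C,D);")
  expect_error(score_character(tri, col_from_states(c("0", "1", "0", "1"),
                                                    LETTERS[1:4])),
               "binary")
})

test_that("gap-free characters score exactly the textbook Fitch length", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(5:15, 1)
    taxa <- paste0("t", 1:n)
    phy <- random_addition_tree(taxa)
    states <- sample(c("0", "1", "2"), n, replace = TRUE)
    col <- col_from_states(states, taxa)
    expect_equal(full_pass_total(phy, col),
                 phangorn_fitch_length(phy, stats::setNames(states, taxa),
                                       c("0", "1", "2")))
  }
})

test_that("characters with few gaps equal the gap-as-missing length", {
  set.seed(34)
  for (rep in 1:60) {
    n <- sample(5:12, 1)
    taxa <- paste0("t", 1:n)
    phy <- random_addition_tree(taxa)
    states <- sample(c("0", "1", "?"), n, replace = TRUE)
    k <- sample(0:2, 1)
    if (k > 0) states[sample(n, k)] <- "-"
    if (!any(states %in% c("0", "1"))) next
    col <- col_from_states(states, taxa)
    expect_equal(score_character(phy, col)$total,
                 fitch_missing_length(phy, col))
    expect_equal(full_pass_total(phy, col),
                 fitch_missing_length(phy, col))
  }
})

test_that("tree score is invariant to rerooting", {
  set.seed(35)
  done <- 0
  while (done < 25) {
    n <- sample(5:9, 1)
    taxa <- paste0("t", 1:n)
    phy <- random_addition_tree(taxa)
    states <- sample(c("0", "1", "-", "?"), n, replace = TRUE,
                     prob = c(.3, .25, .35, .1))
    if (sum(states == "-") < 3 || !any(states %in% c("0", "1"))) next
    done <- done + 1
    col <- col_from_states(states, taxa)
    tot <- score_character(phy, col)$total
    for (r in all_rerootings(phy)) {
      expect_equal(score_character(r, col)$total, tot)
    }
  }
})
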