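test_that("NNI neighbourhoods have the expected size and symmetry", {
  t4 <- parse_newick("((A,B),(C,D));")
  nn4 <- nni_neighbors(t4)
  expect_length(nn4, 2L)
  expect_false(canonical_id(t4) %in% vapply(nn4, canonical_id,
                                            character(1)))
  expect_length(nni_neighbors(parse_newick("(((A,B),C),(D,E));")), 4L)
  # symmetric relation
  back <- vapply(nni_neighbors(nn4[[1]]), canonical_id, character(1))
  expect_true(canonical_id(t4) %in% back)
  expect_error(nni_neighbors(parse_newick("(A,(B,C));")), "4 leaves")
})

test_that("SPR neighbourhoods contain the NNI neighbourhoods", {
  t4 <- parse_newick("((A,B),(C,D));")
  expect_setequal(vapply(spr_neighbors(t4), canonical_id, character(1)),
                  vapply(nni_neighbors(t4), canonical_id, character(1)))
  set.seed(61)
  t7 <- random_addition_tree(paste0("t", 1:7))
  spr_ids <- vapply(spr_neighbors(t7), canonical_id, character(1))
  nni_ids <- vapply(nni_neighbors(t7), canonical_id, character(1))
  expect_true(all(nni_ids %in% spr_ids))
  # the input topology is never its own neighbour
  expect_false(canonical_id(t7) %in% spr_ids)
  # unrooted SPR neighbourhood size: 2(n-3)(2n-7)
  expect_length(spr_ids, 2 * (7 - 3) * (2 * 7 - 7))
})

test_that("topology enumeration is complete and canonical", {
  t5 <- all_topologies(paste0("t", 1:5))
  expect_length(t5, 15L)
  expect_length(unique(vapply(t5, canonical_id, character(1))), 15L)
  skip_if_not_installed("phangorn")
  ref <- phangorn::allTrees(6, rooted = FALSE,
                            tip.label = paste0("t", 1:6))
  mine <- all_topologies(paste0("t", 1:6))
  expect_setequal(vapply(mine, canonical_id, character(1)),
                  vapply(ref, canonical_id, character(1)))
})

test_that("the ratchet recovers the generating tree of a congruent matrix", {
  true <- parse_newick("(((A,B),C),((D,E),F));")
  m <- mat_from_rows(c("110", "110", "100", "001", "001", "000"),
                     c("A", "B", "C", "D", "E", "F"))
  ex <- exhaustive_search(m, "missing")
  expect_true(canonical_id(true) %in% ex$ids)
  expect_equal(ex$score, 3)       # each split character changes once
  rs <- ratchet_search(m, search_config("missing", ratchet_iterations = 8,
                                        stop_after_no_improvement = 4,
                                        seed = 42))
  expect_equal(rs$score, ex$score)
  expect_setequal(rs$ids, ex$ids)
})

test_that("the ratchet finds every optimum of a single character", {
  m <- mat_from_rows(c("0", "0", "1", "1", "0"))
  ex <- exhaustive_search(m, "inapplicable")
  rs <- ratchet_search(m, search_config("inapplicable",
                                        ratchet_iterations = 10,
                                        stop_after_no_improvement = 5,
                                        seed = 7))
  expect_equal(rs$score, ex$score)
  expect_setequal(rs$ids, ex$ids)
})

test_that("searches are reproducible and never worse than their start", {
  set.seed(62)
  phy <- simulate_tree(7, seed = 3)
  m <- simulate_hierarchy(phy, hierarchy_spec(n_dependent = 4), seed = 3)
  cfg <- search_config("inapplicable", ratchet_iterations = 5,
                       stop_after_no_improvement = 3, seed = 11)
  r1 <- ratchet_search(m, cfg)
  r2 <- ratchet_search(m, cfg)
  expect_identical(r1$ids, r2$ids)
  expect_identical(r1$score, r2$score)
  # monotone best-score log
  expect_true(all(diff(r1$score_log) <= 0))
  expect_s3_class(glance(r1), "tbl_df")
})

test_that("search configuration is validated", {
  expect_error(search_config(perturb_fraction = 0))
  expect_error(search_config(ratchet_iterations = 0))
  expect_error(exhaustive_search(
    simulate_hierarchy(simulate_tree(12, 1), seed = 1), "missing"),
    "too many taxa")
})
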