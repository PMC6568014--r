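test_that("simulated trees are binary Yule topologies with unit lengths", {
  phy <- simulate_tree(10, seed = 2)
  expect_length(phy$tip.label, 10L)
  expect_true(ape::is.binary(phy) && ape::is.rooted(phy))
  expect_true(all(phy$edge.length == 1))
  expect_equal(write_newick(simulate_tree(10, seed = 2)),
               write_newick(phy))
  expect_false(write_newick(simulate_tree(10, seed = 3)) ==
                 write_newick(phy))
  expect_error(simulate_tree(3), "at least 4")
})

test_that("dependent characters are inapplicable exactly where the
           principal structure is absent", {
  for (seed in 1:10) {
    phy <- simulate_tree(12, seed = seed)
    m <- simulate_hierarchy(phy, hierarchy_spec(n_dependent = 3,
                                                missing_rate = 0),
                            seed = seed)
    tok <- vapply(seq_along(m$taxa), function(i)
      inappfitch:::cell_token(m$columns[[1]], i), character(1))
    principal_absent <- tok == "0"
    for (j in 2:4) {
      dep_gap <- m$columns[[j]]$masks == 1L
      expect_identical(unname(dep_gap), unname(principal_absent))
    }
  }
})

test_that("simulation is reproducible and responds to its options", {
  phy <- simulate_tree(9, seed = 5)
  m1 <- simulate_hierarchy(phy, hierarchy_spec(), seed = 5)
  m2 <- simulate_hierarchy(phy, hierarchy_spec(), seed = 5)
  expect_identical(lapply(m1$columns, `[[`, "masks"),
                   lapply(m2$columns, `[[`, "masks"))
  # near-zero rates: principal invariant (present ancestrally), dependents
  # fully applicable
  m0 <- simulate_hierarchy(phy, hierarchy_spec(gain_rate = 1e-9,
                                               loss_rate = 1e-9,
                                               dependent_rate = 1e-9),
                           seed = 5)
  expect_equal(length(m0$columns[[1]]$alphabet$applicable), 1L)
  expect_true(all(vapply(m0$columns[-1], n_inapplicable, integer(1)) == 0L))
  # missing injection hits roughly the requested fraction of cells
  mm <- simulate_hierarchy(phy, hierarchy_spec(missing_rate = 0.5),
                           seed = 6)
  miss <- mean(unlist(lapply(mm$columns, `[[`, "missing")))
  expect_gt(miss, 0.2)
  expect_lt(miss, 0.8)
  expect_error(hierarchy_spec(missing_rate = 1))
  expect_error(hierarchy_spec(gain_rate = 0))
})

test_that("neomorphic dependents are binary and recodable", {
  phy <- simulate_tree(10, seed = 7)
  m <- simulate_hierarchy(phy, hierarchy_spec(neomorphic_dependent = TRUE,
                                              n_dependent_states = 5),
                          seed = 7)
  for (j in seq_along(m$columns)[-1]) {
    col <- m$columns[[j]]
    expect_lte(length(col$alphabet$applicable), 2L)
    if (n_inapplicable(col) > 0 && "0" %in% col$alphabet$applicable) {
      expect_equal(n_inapplicable(recode_neomorphic(col, "0")), 0L)
    }
  }
})

test_that("the generating tree scores no worse than random trees on
           average", {
  deltas <- numeric(0)
  for (seed in 1:30) {
    phy <- simulate_tree(8, seed = seed)
    m <- simulate_hierarchy(phy, hierarchy_spec(n_dependent = 4),
                            seed = seed)
    true_score <- score_matrix(phy, m, "inapplicable")$total
    set.seed(seed + 1000)
    rnd <- random_addition_tree(m$taxa)
    rnd_score <- score_matrix(rnd, m, "inapplicable")$total
    deltas <- c(deltas, rnd_score - true_score)
  }
  expect_gte(mean(deltas), 0)
})
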