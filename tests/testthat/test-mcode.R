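test_that("vertex weighting follows the core-density definition", {
  # degree-1 endpoints fall below the degree cutoff and weigh 0
  edge <- mk_graph(rbind(c("A", "B")))
  expect_equal(unname(mcode_weights(edge)), c(0, 0))

  # K4: closed neighborhood is K4 itself, highest core k = 3,
  # loop-inclusive density 6/16, weight 3 * 6/16 = 1.125
  k4 <- mk_complete(4)
  expect_equal(unname(mcode_weights(k4)), rep(1.125, 4))

  # automorphic vertices of a 5-cycle weigh equally: neighborhood is a
  # 3-path (1-core, density 2/9)
  c5 <- mk_cycle(5)
  w <- mcode_weights(c5)
  expect_equal(unname(w), rep(2 / 9, 5), tolerance = 1e-12)
})

test_that("haircut prunes singly-connected periphery to a fixed point", {
  g <- mk_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "D")))
  expect_equal(mcode_haircut(c("A", "B", "C", "D"), g), c("A", "B", "C"))
  # a path dissolves entirely under iteration
  p4 <- mk_path(4)
  expect_length(mcode_haircut(paste0("P", 1:4), p4), 0)
  # a clique is untouched
  k5 <- mk_complete(5)
  expect_equal(mcode_haircut(paste0("K", 1:5), k5), paste0("K", 1:5))
})

test_that("cluster score is internal edges over members", {
  expect_equal(mcode_score(13, 78), 6)
  expect_equal(mcode_score(13, 40), 40 / 13)
  expect_equal(mcode_score(4, 0), 0)
  expect_error(mcode_score(0, 1), "v_count")
})

test_that("complex detection recovers a maximal dense core", {
  k4 <- mk_complete(4)
  cls <- mcode(k4)
  expect_length(cls, 1)
  expect_equal(cls[[1]]$members, paste0("K", 1:4))
  expect_equal(cls[[1]]$n_edges, 6L)
  expect_equal(cls[[1]]$score, 1.5)
})

test_that("uniformly weighted bridged cliques grow into one cluster", {
  # both K5s and the bridge endpoints share weight 4 * 10/25 = 1.6, so the
  # seeded growth crosses the bridge and returns the whole 10-node graph
  g <- mk_two_cliques(5)
  w <- mcode_weights(g)
  expect_equal(unname(w), rep(1.6, 10), tolerance = 1e-12)
  cls <- mcode(g)
  expect_length(cls, 1)
  expect_equal(cls[[1]]$n_members, 10L)
  expect_equal(cls[[1]]$n_edges, 21L)
  expect_equal(cls[[1]]$score, 2.1)
})

test_that("a planted dense module is found inside a sparse background", {
  core <- t(utils::combn(paste0("M", 1:5), 2))
  chain <- cbind(paste0("S", 1:20), paste0("S", 2:21))
  g <- mk_graph(rbind(core, chain, c("M1", "S1")))
  cls <- mcode(g)
  expect_length(cls, 1)
  expect_equal(cls[[1]]$members, paste0("M", 1:5))
})

test_that("clusters are disjoint, connected, and survive their own filters", {
  fix <- generate_string_fixture(small_fixture_spec())
  net <- build_network(fix$edges, fix$annotations)
  params <- mcode_params()
  cls <- mcode(net, params)
  all_members <- unlist(lapply(cls, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)
  for (cl in cls) {
    sub <- igraph::induced_subgraph(net, cl$members)
    expect_true(igraph::is_connected(sub))
    expect_gte(max(igraph::coreness(sub)), params$k_core)
    expect_equal(cl$score, cl$n_edges / cl$n_members)
    # haircut already at fixed point
    expect_equal(mcode_haircut(cl$members, net), cl$members)
  }
  # ranking: scores non-increasing
  scores <- vapply(cls, `[[`, 1, "score")
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("growth depth beyond the graph diameter changes nothing", {
  fix <- generate_string_fixture(small_fixture_spec(rng_seed = 21L))
  net <- build_network(fix$edges, fix$annotations)
  a <- mcode(net, mcode_params(max_depth = 100))
  b <- mcode(net, mcode_params(max_depth = 200))
  expect_identical(a, b)
})

test_that("fluff admits qualifying boundary members without consuming them", {
  # K4 core with one boundary vertex attached by a single edge: haircut
  # would drop it, fluff (haircut off) pulls it in when its neighborhood
  # density passes the threshold
  g <- mk_graph(rbind(t(utils::combn(paste0("K", 1:4), 2)), c("K1", "X")))
  base <- mcode(g, mcode_params(haircut = FALSE))
  expect_false("X" %in% base[[1]]$members)
  fl <- mcode(g, mcode_params(haircut = FALSE, fluff = TRUE,
                              fluff_density = 0.1))
  expect_true("X" %in% fl[[1]]$members)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(mcode_params(degree_cutoff = 0), "degree_cutoff")
  expect_error(mcode_params(node_score_cutoff = 1.5), "node_score_cutoff")
})
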