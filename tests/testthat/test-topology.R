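test_that("degree distribution counts nodes exactly, including isolates", {
  tri <- mk_complete(3)
  dd <- degree_distribution(tri)
  expect_equal(dd$counts, c("2" = 3L))
  expect_equal(dd$n_total, 3)

  star <- mk_star(5)
  dd2 <- degree_distribution(star)
  expect_equal(dd2$counts[["1"]], 5L)
  expect_equal(dd2$counts[["5"]], 1L)

  lone <- build_network(
    parse_edge_table("A\tB\t0.9\tx"),
    data.frame(symbol = "Z", subfamily = "ARF", is_gtpase = TRUE))
  dd3 <- degree_distribution(lone)
  expect_equal(dd3$counts[["0"]], 1L)
  # probabilities sum to one
  expect_equal(sum(dd3$counts) / dd3$n_total, 1)
})

test_that("log-log OLS recovers an exact power law to machine precision", {
  k <- 1:20
  dd <- stats::setNames(100 * k^-2, k)
  fit <- fit_power_law(dd)
  expect_equal(fit$gamma, 2, tolerance = 1e-12)
  expect_equal(fit$prefactor, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fit on a rounded heavy-tail table matches the closed-form OLS", {
  k <- 1:50
  nk <- round(335 * k^-1.38)
  keep <- nk > 0
  ref <- oracle_loglog_slope(k[keep], nk[keep])
  fit <- fit_power_law(data.frame(k = k, n_k = nk))
  expect_equal(fit$gamma, -ref$slope, tolerance = 1e-12)
  expect_equal(fit$r_squared, ref$r2, tolerance = 1e-12)
  expect_lt(abs(fit$gamma - 1.38), 0.05)
  expect_error(fit_power_law(stats::setNames(c(5, 3), c(1, 2))), ">= 3")
})

test_that("local clustering matches brute-force triple enumeration", {
  tri <- mk_complete(3)
  expect_equal(local_clustering(tri, "K1"), 1)
  star <- mk_star(5)
  expect_equal(local_clustering(star, "HUB"), 0)
  expect_error(local_clustering(star, "NOPE"), "not in network")

  g <- rand_graph(20, 0.25, seed = 5)
  ref <- oracle_local_clustering(g)
  for (v in names(ref)) {
    expect_equal(local_clustering(g, v), unname(ref[v]), tolerance = 1e-12)
  }
})

test_that("global clustering averages all nodes, low-degree nodes as zero", {
  expect_equal(global_clustering(mk_complete(5))$global, 1)
  expect_equal(global_clustering(mk_path(3))$global, 0)

  # triangle plus pendant: three nodes at 1, pendant and its neighbor diluted
  g <- mk_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "D")))
  ref <- oracle_local_clustering(g)
  rep_ <- global_clustering(g)
  expect_equal(rep_$global, mean(ref), tolerance = 1e-12)
  expect_true(all(rep_$per_node >= 0 & rep_$per_node <= 1))
})

test_that("path-length statistics enumerate unordered reachable pairs", {
  k4 <- mk_complete(4)
  ps <- path_length_stats(k4)
  expect_equal(ps$histogram, c("1" = 6L))
  expect_equal(ps$mean, 1)

  p4 <- mk_path(4)
  ps2 <- path_length_stats(p4)
  expect_equal(ps2$histogram, c("1" = 3L, "2" = 2L, "3" = 1L))
  expect_equal(ps2$mean, 10 / 6, tolerance = 1e-12)

  # pair count over a disconnected graph: sum of C(size, 2) per component
  two <- net_union(list(mk_complete(3, "X"), mk_path(4, "Y")))
  ps3 <- path_length_stats(two)
  expect_equal(ps3$n_pairs, choose(3, 2) + choose(4, 2))
  expect_error(path_length_stats(build_network(
    parse_edge_table(character()),
    data.frame(symbol = "A", subfamily = "RHO", is_gtpase = TRUE))),
    "at least one edge")
})

test_that("components match a union-find oracle and isolates are listed", {
  two_tri <- net_union(list(mk_complete(3, "X"), mk_complete(3, "Y")))
  comp <- network_components(two_tri)
  expect_equal(comp$sizes, c(3, 3))

  g <- build_network(
    parse_edge_table(c("A\tB\t0.9\tx", "B\tC\t0.9\tx", "C\tA\t0.9\tx")),
    data.frame(symbol = "X", subfamily = "RAB", is_gtpase = TRUE))
  expect_equal(network_components(g)$isolates, "X")

  r <- rand_graph(40, 0.05, seed = 9)
  expect_equal(network_components(r)$components, oracle_components(r))
})

test_that("hub identification: both rules pick the star center", {
  star <- mk_star(6)
  expect_equal(identify_hubs(star, "degree_gap")$hubs, "HUB")
  expect_equal(identify_hubs(star, "top_fraction", 0.2)$hubs, "HUB")
  expect_error(identify_hubs(star, "top_fraction", 1.5), "\\(0, 1\\)")
})

test_that("degree-gap rule recovers the two hub tiers of a ladder sequence", {
  # mirrors the published degree sequence shape: four dominant degrees, a
  # gap, four second-tier degrees, a bigger drop to the bulk
  g <- mk_degree_ladder(c(134, 110, 96, 77, 53, 45, 38, 35, 15, 14, 13),
                        pad_pairs = 120)
  hr <- identify_hubs(g, "degree_gap")
  expect_equal(hr$hubs, sprintf("H%02d", 1:4))
  expect_equal(hr$second_tier, sprintf("H%02d", 5:8))
  # every hub degree >= every non-hub degree
  deg <- igraph::degree(g)
  expect_gte(min(deg[hr$hubs]), max(deg[setdiff(names(deg), hr$hubs)]))
})

test_that("degree-gap rule isolates a planted high-degree block exactly", {
  g <- mk_degree_ladder(c(rep(15, 4), rep(3, 12)), pad_pairs = 60)
  hr <- identify_hubs(g, "degree_gap")
  expect_setequal(hr$hubs, sprintf("H%02d", 1:4))
})

test_that("degree shares express hub connectivity as percentages", {
  expect_equal(round(degree_share(c(134, 110, 96, 77), 1943), 1), 21.5)
  expect_error(degree_share(5, 0), "positive")
})
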