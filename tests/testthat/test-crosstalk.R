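test_that("subfamily networks keep only seed-incident edges", {
  recs <- parse_edge_table(c("RAC1\tPAK1\t0.9\tx", "PAK1\tGRB2\t0.9\tx"))
  sn <- subfamily_network(recs, "RAC1", "RHO")
  expect_setequal(sn$members, c("RAC1", "PAK1"))
  expect_equal(igraph::ecount(sn$network), 1)

  # seeds with no records stay as isolated members
  sn2 <- subfamily_network(recs, c("RHOA", "RHOB"), "RHO")
  expect_setequal(sn2$members, c("RHOA", "RHOB"))
  expect_equal(igraph::ecount(sn2$network), 0)
  expect_error(subfamily_network(recs, character(), "RHO"), "non-empty")
})

test_that("shared proteins are grouped by exact subfamily combination", {
  recs <- parse_edge_table(c(
    "RAC1\tSHARED4\t0.9\tx", "HRAS\tSHARED4\t0.9\tx",
    "RAB5A\tSHARED4\t0.9\tx", "ARF1\tSHARED4\t0.9\tx",
    "RAC1\tDUO\t0.9\tx", "HRAS\tDUO\t0.9\tx",
    "RAC1\tONLYRHO\t0.9\tx"))
  subnets <- list(subfamily_network(recs, "RAC1", "RHO"),
                  subfamily_network(recs, "HRAS", "RAS"),
                  subfamily_network(recs, "RAB5A", "RAB"),
                  subfamily_network(recs, "ARF1", "ARF"))
  ov <- shared_proteins(subnets)
  expect_equal(ov$by_count[["4"]], "SHARED4")
  expect_equal(ov$by_count[["2"]], "DUO")
  expect_equal(unname(ov$by_combination["RAS+RHO"]), 1L)
  expect_equal(ov$n_shared, 2)
  expect_false("ONLYRHO" %in% names(ov$membership[
    vapply(ov$membership, length, 1L) >= 2]))

  disjoint <- list(subfamily_network(recs[7, ], "RAC1", "RHO"),
                   subfamily_network(recs[3, ], "RAB5A", "RAB"))
  expect_equal(shared_proteins(disjoint)$n_shared, 0)
  expect_error(shared_proteins(subnets[1]), "at least 2")
})

test_that("seed GTPases can be included in or excluded from the overlap", {
  # HRAS is a RAS seed but also a first neighbor of the RHO seed
  recs <- parse_edge_table(c("RAC1\tHRAS\t0.9\tx", "HRAS\tSOS1\t0.9\tx"))
  subnets <- list(subfamily_network(recs, "RAC1", "RHO"),
                  subfamily_network(recs, "HRAS", "RAS"))
  with_seeds <- shared_proteins(subnets, include_seeds = TRUE)
  expect_true("HRAS" %in% names(with_seeds$membership[
    vapply(with_seeds$membership, length, 1L) >= 2]))
  without <- shared_proteins(subnets, include_seeds = FALSE)
  expect_equal(without$n_shared, 0)
})

test_that("planted fixture overlaps are recovered exactly", {
  fix <- generate_string_fixture(small_fixture_spec())
  subnets <- lapply(names(fix$seed_table), function(lab)
    subfamily_network(fix$edges, fix$seed_table[[lab]], lab))
  ov <- shared_proteins(subnets)
  planted <- fix$spec$planted_overlaps
  got <- ov$by_combination[order(names(ov$by_combination))]
  want <- planted[order(names(planted))]
  expect_equal(as.integer(got), as.integer(want), ignore_attr = TRUE)
  expect_equal(names(got), names(want))
  expect_equal(ov$n_shared, sum(planted))
  # membership size equals the number of subnetworks a protein neighbors:
  # brute-force incidence scan
  for (prt in names(ov$membership)) {
    touches <- vapply(fix$seed_table, function(seeds) {
      any(fix$edges$protein_a == prt & fix$edges$protein_b %in% seeds) ||
        any(fix$edges$protein_b == prt & fix$edges$protein_a %in% seeds)
    }, logical(1))
    is_seed <- vapply(fix$seed_table, function(seeds) prt %in% seeds,
                      logical(1))
    expect_setequal(ov$membership[[prt]],
                    names(touches)[touches | is_seed])
  }
})

test_that("first neighbors come back sorted and exact", {
  tri <- mk_complete(3)
  expect_equal(first_neighbors_of(tri, "K1"), c("K2", "K3"))
  g <- build_network(
    parse_edge_table("A\tB\t0.9\tx"),
    data.frame(symbol = "Z", subfamily = "RAN", is_gtpase = TRUE))
  expect_length(first_neighbors_of(g, "Z"), 0)
  expect_error(first_neighbors_of(g, "Q"), "not in network")

  r <- rand_graph(15, 0.3, seed = 4)
  adj <- oracle_adjacency(r)
  for (v in names(adj)) {
    expect_equal(first_neighbors_of(r, v), sort(unique(adj[[v]])))
  }
})

test_that("coverage counts seeds with at least one interaction", {
  seeds <- list(RHO = c("RAC1", "RHOA", "RHOB", "RHOC", "RHOD"),
                RAS = c("HRAS", "KRAS"))
  none <- coverage_stats(seeds, empty_recs <- data.frame(
    protein_a = character(), protein_b = character(),
    confidence = numeric(), evidence = character()))
  expect_equal(none$n_with_interactions, c(0, 0))

  recs <- parse_edge_table(c("RAC1\tX\t0.9\tx", "RHOA\tY\t0.9\tx",
                             "Z\tRHOB\t0.9\tx", "HRAS\tKRAS\t0.9\tx"))
  cov <- coverage_stats(seeds, recs)
  expect_equal(cov$n_searched, c(5, 2))
  expect_equal(cov$n_with_interactions, c(3, 2))
  expect_true(all(cov$n_with_interactions <= cov$n_searched))
})
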