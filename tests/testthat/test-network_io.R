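test_that("edge-table parsing normalizes symbols and preserves order", {
  expect_equal(nrow(parse_edge_table(character())), 0)
  expect_equal(nrow(parse_edge_table("")), 0)

  recs <- parse_edge_table(c("RAC1\tCDC42\t0.9\texp",
                             "RAC1\tPAK1\t0.5\texp",
                             " rac1 \tpak1\t0.5\texp"))
  expect_equal(nrow(recs), 3)
  expect_equal(recs[3, c("protein_a", "protein_b", "confidence")],
               recs[2, c("protein_a", "protein_b", "confidence")],
               ignore_attr = TRUE)

  with_header <- parse_edge_table(
    c("protein_a\tprotein_b\tscore\tevidence", "A\tB\t0.7\texp"))
  expect_equal(nrow(with_header), 1)
  expect_equal(with_header$confidence, 0.7)

  expect_error(parse_edge_table("A\tB\t1.4\texp"), "outside \\[0, 1\\].*line 1")
  expect_error(parse_edge_table(c("A\tB\t0.5\tx", "A\tB")), "line 2")
  expect_error(parse_edge_table(" \tB\t0.5\tx"), "empty protein symbol")
})

test_that("SIF rows fan out to pairwise records at confidence 1", {
  recs <- parse_edge_table(c("RAC1 pp PAK1 GRB2", "lone"), format = "sif")
  expect_equal(recs$protein_a, c("RAC1", "RAC1"))
  expect_equal(recs$protein_b, c("PAK1", "GRB2"))
  expect_equal(recs$confidence, c(1, 1))
  expect_equal(recs$evidence, c("pp", "pp"))
  expect_error(parse_edge_table("A pp", format = "sif"), "line 1")
})

test_that("records round-trip through the canonical TSV writer", {
  withr::with_seed(42, {
    n <- 50
    syms <- sprintf("GENE%03d", 1:40)
    recs <- data.frame(
      protein_a = sample(syms, n, replace = TRUE),
      protein_b = sample(syms, n, replace = TRUE),
      confidence = round(runif(n, 0.4, 1), 3),
      evidence = sample(c("exp", "db"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    recs <- recs[recs$protein_a != recs$protein_b, ]
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(recs, path)
  back <- parse_edge_table(path)
  canon <- function(df) {
    lo <- pmin(df$protein_a, df$protein_b)
    hi <- pmax(df$protein_a, df$protein_b)
    df <- data.frame(a = lo, b = hi, confidence = df$confidence,
                     evidence = df$evidence)
    df[order(df$a, df$b, df$confidence), ]
  }
  expect_equal(canon(back), canon(recs), ignore_attr = TRUE)
})

test_that("confidence filtering keeps the threshold inclusively", {
  recs <- data.frame(protein_a = c("A", "A", "A"),
                     protein_b = c("B", "C", "D"),
                     confidence = c(0.39, 0.40, 0.41),
                     evidence = "exp", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_confidence(recs, 0)), 3)
  kept <- filter_by_confidence(recs, 0.4)
  expect_equal(kept$protein_b, c("C", "D"))
  # applying the filter twice changes nothing
  expect_identical(filter_by_confidence(kept, 0.4), kept)
  expect_error(filter_by_confidence(recs, 1.2), "\\[0, 1\\]")
})

test_that("network construction drops self-loops and collapses duplicates", {
  recs <- parse_edge_table(c("A\tB\t0.9\tx", "B\tA\t0.8\tx", "C\tC\t0.5\tx"))
  g <- build_network(recs)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))

  # self-loop node C survives only via the annotation table
  anno <- data.frame(symbol = "C", subfamily = "RAB", is_gtpase = TRUE)
  g2 <- build_network(recs, anno)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_equal(unname(igraph::degree(g2)["C"]), 0)
  expect_equal(igraph::V(g2)$subfamily[igraph::V(g2)$name == "C"], "RAB")

  tri <- data.frame(protein_a = rep(c("A", "B", "C"), 2),
                    protein_b = rep(c("B", "C", "A"), 2),
                    confidence = 0.9, evidence = "x")
  expect_equal(igraph::ecount(build_network(tri)), 3)
})

test_that("edge count equals the distinct canonical pair count", {
  withr::with_seed(7, {
    syms <- sprintf("G%02d", 1:25)
    recs <- data.frame(protein_a = sample(syms, 100, replace = TRUE),
                       protein_b = sample(syms, 100, replace = TRUE),
                       confidence = 0.9, evidence = "x",
                       stringsAsFactors = FALSE)
  })
  keep <- recs$protein_a != recs$protein_b
  d <- length(unique(paste(pmin(recs$protein_a, recs$protein_b),
                           pmax(recs$protein_a, recs$protein_b))[keep]))
  g <- build_network(recs)
  expect_equal(igraph::ecount(g), d)
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("network union is idempotent, additive, and label-aware", {
  recs <- parse_edge_table(c("A\tB\t0.9\tx", "B\tC\t0.8\tx", "C\tA\t0.7\tx"))
  g <- build_network(recs)
  u <- net_union(list(g, g))
  expect_equal(igraph::vcount(u), igraph::vcount(g))
  expect_equal(igraph::ecount(u), igraph::ecount(g))

  g2 <- build_network(parse_edge_table(
    c("D\tE\t0.9\tx", "E\tF\t0.8\tx", "F\tD\t0.7\tx")))
  u2 <- net_union(list(g, g2))
  expect_equal(igraph::vcount(u2), 6)
  expect_equal(igraph::ecount(u2), 6)

  # overlap o edges: |E| = |E1| + |E2| - o
  g3 <- build_network(parse_edge_table(c("A\tB\t0.9\tx", "B\tD\t0.9\tx")))
  u3 <- net_union(list(g, g3))
  expect_equal(igraph::ecount(u3),
               igraph::ecount(g) + igraph::ecount(g3) - 1)

  # OTHER is absorbed; two specific labels conflict
  anno_rho <- data.frame(symbol = "A", subfamily = "RHO", is_gtpase = TRUE)
  anno_ras <- data.frame(symbol = "A", subfamily = "RAS", is_gtpase = TRUE)
  ga <- build_network(recs, anno_rho)
  gb <- build_network(recs)
  merged <- net_union(list(ga, gb))
  expect_equal(igraph::V(merged)$subfamily[igraph::V(merged)$name == "A"],
               "RHO")
  gc <- build_network(recs, anno_ras)
  expect_error(net_union(list(ga, gc)), "conflicting subfamily")
})

test_that("blacklisted interactions are excluded as unordered pairs", {
  seven <- rbind(c("RAC1", "CDC42"), c("HRAS", "RHEB"), c("HRAS", "RAP1B"),
                 c("HRAS", "ARHGEF1"), c("RHOA", "PLEKHG2"),
                 c("RAB5A", "RAB7A"), c("RAB5A", "RIT2"))
  extra <- rbind(c("RAC1", "PAK1"), c("RHOA", "ROCK1"))
  recs <- data.frame(protein_a = c(seven[, 2], extra[, 1]),
                     protein_b = c(seven[, 1], extra[, 2]),
                     confidence = 0.9, evidence = "x",
                     stringsAsFactors = FALSE)
  g <- build_network(recs)
  expect_equal(igraph::ecount(g), 9)
  g2 <- exclude_edges(g, seven)
  expect_equal(igraph::ecount(g2), 2)

  expect_equal(igraph::ecount(exclude_edges(g, NULL)), 9)
  expect_equal(igraph::ecount(exclude_edges(g, rbind(c("ZZZ", "YYY")))), 9)
})

test_that("confidence summary reports population moments and closed bins", {
  recs <- data.frame(protein_a = "A", protein_b = c("B", "C", "D"),
                     confidence = c(0.4, 0.6, 0.8), evidence = "x")
  cs <- confidence_summary(recs)
  expect_equal(cs$mean, 0.6)
  expect_equal(cs$sd, sqrt(0.08 / 3), tolerance = 1e-12)
  expect_equal(sum(cs$bin_counts), cs$n)

  same <- confidence_summary(data.frame(protein_a = "A", protein_b = "B",
                                        confidence = rep(0.5, 4),
                                        evidence = "x"))
  expect_equal(same$mean, 0.5)
  expect_equal(same$sd, 0)

  # a perfect score lands in the final (closed) bin
  top <- confidence_summary(data.frame(protein_a = "A", protein_b = "B",
                                       confidence = 1.0, evidence = "x"))
  expect_equal(unname(top$bin_counts[length(top$bin_counts)]), 1)
  expect_error(confidence_summary(empty <- data.frame(confidence = numeric())),
               "no records")
})

test_that("curation report renders the confirmed percentage to one decimal", {
  expect_equal(curation_report(429, 7)$pct_confirmed_rendered, 98.4)
  expect_equal(curation_report(100, 0)$pct_confirmed_rendered, 100.0)
  expect_equal(curation_report(429, 12)$pct_confirmed_rendered, 97.2)
  expect_error(curation_report(0, 0), "positive")
  expect_error(curation_report(10, 11), "n_considered")
})
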