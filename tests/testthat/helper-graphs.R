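# Small deterministic graph builders used across tests.

mk_graph <- function(el) {
  igraph::graph_from_edgelist(as.matrix(el), directed = FALSE)
}

mk_path <- function(n, prefix = "P") {
  nm <- paste0(prefix, seq_len(n))
  mk_graph(cbind(nm[-n], nm[-1]))
}

mk_cycle <- function(n, prefix = "C") {
  nm <- paste0(prefix, seq_len(n))
  mk_graph(cbind(nm, nm[c(2:n, 1)]))
}

mk_complete <- function(n, prefix = "K") {
  nm <- paste0(prefix, seq_len(n))
  mk_graph(t(utils::combn(nm, 2)))
}

mk_star <- function(n_leaves, center = "HUB", prefix = "L") {
  mk_graph(cbind(center, paste0(prefix, seq_len(n_leaves))))
}

# Two K5 cliques joined by a single bridge edge A1-B1.
mk_two_cliques <- function(k = 5) {
  el <- rbind(t(utils::combn(paste0("A", seq_len(k)), 2)),
              t(utils::combn(paste0("B", seq_len(k)), 2)),
              c("A1", "B1"))
  mk_graph(el)
}

# Graph realizing a prescribed top-degree sequence: each "hub" i is a star
# center with degrees[i] private leaves, padded with extra leaf-leaf edges
# so the top decile is wide enough to contain all hubs.
mk_degree_ladder <- function(degrees, pad_pairs = 20) {
  stopifnot(all(degrees >= 1))
  rows <- list()
  for (i in seq_along(degrees)) {
    hub <- sprintf("H%02d", i)
    rows[[i]] <- cbind(hub, sprintf("H%02dL%03d", i, seq_len(degrees[i])))
  }
  pads <- cbind(sprintf("PADA%03d", seq_len(pad_pairs)),
                sprintf("PADB%03d", seq_len(pad_pairs)))
  mk_graph(rbind(do.call(rbind, rows), pads))
}

# A small reproducible random graph (via the package ER generator).
rand_graph <- function(n, p, seed) generate_er(n, p, rng_seed = seed)

small_fixture_spec <- function(rng_seed = 11L) {
  fixture_spec(
    subfamily_sizes = c(RHO = 6, RAS = 6, RAB = 5, ARF = 4, RAN = 1, RGK = 2),
    connected_per_subfamily = c(RHO = 5, RAS = 5, RAB = 4, ARF = 3, RAN = 1,
                                RGK = 1),
    n_total = 120, n_edges = 260,
    hub_table = data.frame(
      symbol = c("RAC1", "CDC42", "HRAS", "ARF1"),
      subfamily = c("RHO", "RHO", "RAS", "ARF"),
      degree = c(20, 15, 12, 8), stringsAsFactors = FALSE),
    planted_overlaps = c("RAS+RHO" = 5, "RAB+RHO" = 2,
                         "ARF+RAB+RAS+RHO" = 1),
    rng_seed = rng_seed)
}
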