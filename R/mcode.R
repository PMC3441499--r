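#' Parameters for MCODE-style complex detection
#'
#' Defaults follow the settings used for the GTPase network analysis:
#' degree cutoff 2 (minimum degree for a node to be scored), node score
#' cutoff 0.2 (a node joins a growing cluster if its weight is at least 80%
#' of the seed's weight), K-core filter 3 (clusters lacking a maximally
#' interconnected 3-core are discarded), and haircut on (iterative removal
#' of cluster members with fewer than two within-cluster edges).
#'
#' @param degree_cutoff Minimum degree for a vertex to receive a weight.
#' @param node_score_cutoff Fraction in \[0, 1\] by which a joining node's
#'   weight may fall below the seed's.
#' @param k_core Minimum core number a cluster must contain to be kept.
#' @param haircut Prune singly-connected periphery members iteratively.
#' @param fluff Add boundary neighbours whose closed-neighbourhood density
#'   reaches `fluff_density` (off by default; fluffed members may overlap
#'   between clusters).
#' @param fluff_density Density threshold used when `fluff = TRUE`.
#' @param max_depth Maximum breadth-first growth depth from the seed.
#' @return Object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 3, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1, max_depth = 100) {
  if (degree_cutoff < 1) stop("`degree_cutoff` must be >= 1", call. = FALSE)
  if (node_score_cutoff < 0 || node_score_cutoff > 1) {
    stop("`node_score_cutoff` must lie in [0, 1]", call. = FALSE)
  }
  if (k_core < 1) stop("`k_core` must be >= 1", call. = FALSE)
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff, k_core = k_core,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density, max_depth = max_depth),
            class = "mcode_params")
}

# Loop-inclusive density e / v^2: the convention under which the reported
# cluster score reduces to edges / members.
density_loop_inclusive <- function(v, e) e / v^2

#' MCODE vertex weighting
#'
#' Each vertex with degree at least `degree_cutoff` is weighted by the
#' highest k-core of its closed neighbourhood: weight = core number k times
#' the loop-inclusive density (edges / vertices^2) of that k-core subgraph.
#' Vertices below the degree cutoff weigh 0.
#'
#' @param network An interaction network.
#' @param params An [mcode_params()] object.
#' @return Named numeric vector of vertex weights.
#' @examples
#' k4 <- igraph::make_full_graph(4)
#' igraph::V(k4)$name <- LETTERS[1:4]
#' mcode_weights(k4)  # 3 * 6/16 = 1.125 for every vertex
#' @export
mcode_weights <- function(network, params = mcode_params()) {
  assert_network(network)
  nm <- node_names(network)
  deg <- igraph::degree(network)
  w <- stats::setNames(numeric(length(nm)), nm)
  adj <- igraph::as_adj_list(network)
  for (i in seq_along(nm)) {
    if (deg[i] < params$degree_cutoff) next
    nbhd <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(network, nbhd)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[i] <- kmax * density_loop_inclusive(igraph::vcount(core_sub),
                                          igraph::ecount(core_sub))
  }
  w
}

#' Haircut: prune weakly attached cluster periphery
#'
#' Iteratively removes members with fewer than two edges inside the induced
#' subgraph until a fixed point is reached; a path dissolves entirely while
#' a cycle or clique is untouched.
#'
#' @param members Character vector of cluster member symbols.
#' @param network The network the cluster lives in.
#' @return The surviving member symbols (possibly empty).
#' @export
mcode_haircut <- function(members, network) {
  assert_network(network)
  members <- intersect(members, node_names(network))
  repeat {
    if (length(members) == 0) return(character())
    sub <- igraph::induced_subgraph(network, members)
    deg <- igraph::degree(sub)
    drop <- node_names(sub)[deg < 2]
    if (length(drop) == 0) return(sort(members))
    members <- setdiff(members, drop)
  }
}

#' Cluster score: density times size
#'
#' The reported cluster score is the loop-inclusive density DC = E/V^2
#' multiplied by the member count V, which reduces algebraically to E/V.
#' Rendered to one decimal in tables.
#'
#' @param v_count Number of member proteins (>= 1).
#' @param e_count Number of internal edges.
#' @return The score (unrounded).
#' @examples
#' mcode_score(13, 78)  # 6
#' @export
mcode_score <- function(v_count, e_count) {
  if (v_count < 1) stop("`v_count` must be >= 1", call. = FALSE)
  if (e_count < 0) stop("`e_count` must be >= 0", call. = FALSE)
  density_loop_inclusive(v_count, e_count) * v_count
}

#' MCODE-style molecular complex detection
#'
#' Greedy seeded growth: vertices are weighted by local core density
#' ([mcode_weights()]), then clusters are grown breadth-first from the
#' highest-weight unvisited vertex, admitting neighbours whose weight is at
#' least `(1 - node_score_cutoff)` times the seed's weight, up to
#' `max_depth` steps from the seed. Visited vertices are never reused, so
#' clusters are node-disjoint (unless `fluff` adds shared boundary
#' members). Each grown cluster is haircut-pruned (if enabled), must
#' contain a k-core of at least `k_core` to be kept, and is scored as
#' internal edges divided by member count. Ties in seed selection are
#' broken lexicographically so output is deterministic.
#'
#' @param network An interaction network.
#' @param params An [mcode_params()] object.
#' @return Object of class `mcode_clusters`: list of clusters, each with
#'   `seed`, `members` (sorted), `n_members`, `n_edges`, `density`,
#'   `score`; ranked by score (desc), then size (desc), then seed symbol.
#' @export
mcode <- function(network, params = mcode_params()) {
  assert_network(network)
  w <- mcode_weights(network, params)
  nm <- node_names(network)
  adj <- igraph::as_adj_list(network)
  ord <- order(-w, nm)
  visited <- stats::setNames(logical(length(nm)), nm)
  clusters <- list()
  for (si in ord) {
    if (visited[si] || w[si] <= 0) next
    threshold <- (1 - params$node_score_cutoff) * w[si]
    members_idx <- si
    visited[si] <- TRUE
    frontier <- si
    depth <- 0
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- integer()
      for (f in frontier) {
        for (v in as.integer(adj[[f]])) {
          if (!visited[v] && w[v] >= threshold) {
            visited[v] <- TRUE
            nxt <- c(nxt, v)
          }
        }
      }
      members_idx <- c(members_idx, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    members <- nm[members_idx]
    if (params$haircut) members <- mcode_haircut(members, network)
    if (params$fluff && length(members) > 0) {
      members <- mcode_fluff(members, network, adj, nm, params$fluff_density)
    }
    if (length(members) == 0) next
    sub <- igraph::induced_subgraph(network, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    clusters[[length(clusters) + 1]] <-
      list(seed = nm[si], members = sort(members),
           n_members = as.integer(igraph::vcount(sub)),
           n_edges = as.integer(igraph::ecount(sub)),
           density = density_loop_inclusive(igraph::vcount(sub),
                                            igraph::ecount(sub)),
           score = mcode_score(igraph::vcount(sub), igraph::ecount(sub)))
  }
  if (length(clusters) > 0) {
    ord <- order(-vapply(clusters, `[[`, 1, "score"),
                 -vapply(clusters, `[[`, 1, "n_members"),
                 vapply(clusters, `[[`, "", "seed"))
    clusters <- clusters[ord]
  }
  structure(clusters, class = "mcode_clusters")
}

# Fluff step: admit unvisited boundary neighbours whose closed-neighbourhood
# density reaches the threshold. Fluffed members are not marked visited and
# may therefore appear in more than one cluster.
mcode_fluff <- function(members, network, adj, nm, fluff_density) {
  idx <- match(members, nm)
  boundary <- setdiff(unique(unlist(lapply(idx, function(i)
    as.integer(adj[[i]])))), idx)
  add <- integer()
  for (v in boundary) {
    nbhd <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(network, nbhd)
    if (density_loop_inclusive(igraph::vcount(sub),
                               igraph::ecount(sub)) >= fluff_density) {
      add <- c(add, v)
    }
  }
  sort(c(members, nm[add]))
}

#' @export
print.mcode_clusters <- function(x, ...) {
  if (length(x) == 0) {
    cat("No clusters found\n")
    return(invisible(x))
  }
  for (i in seq_along(x)) {
    cl <- x[[i]]
    cat(sprintf("%2d  score %.1f  %d nodes  %d edges  seed %s\n",
                i, round_half_up(cl$score, 1), cl$n_members, cl$n_edges,
                cl$seed))
  }
  invisible(x)
}
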