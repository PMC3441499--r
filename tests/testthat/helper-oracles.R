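# Brute-force oracles, deliberately independent of the implementation (no
# igraph shortest-path / clustering / component calls): adjacency is read
# once from the edge list and everything else is enumerated directly.

oracle_adjacency <- function(g) {
  el <- igraph::as_edgelist(g)
  nm <- igraph::V(g)$name
  adj <- stats::setNames(lapply(nm, function(x) character()), nm)
  for (r in seq_len(nrow(el))) {
    adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
    adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
  }
  adj
}

# All shortest paths between every unordered pair, by exhaustive DFS over
# simple paths (viable for graphs up to ~12 nodes).
oracle_all_shortest_paths <- function(adj, s, t) {
  best <- Inf
  found <- list()
  walk <- function(path) {
    head <- path[length(path)]
    if (head == t) {
      len <- length(path) - 1
      if (len < best) {
        best <<- len
        found <<- list(path)
      } else if (len == best) {
        found[[length(found) + 1]] <<- path
      }
      return()
    }
    if (length(path) - 1 >= best) return()
    for (nb in adj[[head]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(s)
  list(length = best, paths = found)
}

# Fractional betweenness: each pair splits one unit of credit equally over
# its shortest paths; interior nodes collect the shares.
oracle_betweenness <- function(g) {
  adj <- oracle_adjacency(g)
  nm <- names(adj)
  sc <- stats::setNames(numeric(length(nm)), nm)
  if (length(nm) < 3) return(sc)
  prs <- utils::combn(nm, 2)
  for (j in seq_len(ncol(prs))) {
    res <- oracle_all_shortest_paths(adj, prs[1, j], prs[2, j])
    if (!is.finite(res$length) || res$length < 2) next
    for (p in res$paths) {
      interior <- p[-c(1, length(p))]
      sc[interior] <- sc[interior] + 1 / length(res$paths)
    }
  }
  sc
}

# Strict-count betweenness: a pair credits a node 1 if ANY shortest path
# between them passes through it.
oracle_betweenness_strict <- function(g) {
  adj <- oracle_adjacency(g)
  nm <- names(adj)
  sc <- stats::setNames(numeric(length(nm)), nm)
  if (length(nm) < 3) return(sc)
  prs <- utils::combn(nm, 2)
  for (j in seq_len(ncol(prs))) {
    res <- oracle_all_shortest_paths(adj, prs[1, j], prs[2, j])
    if (!is.finite(res$length) || res$length < 2) next
    interior <- unique(unlist(lapply(res$paths, function(p)
      p[-c(1, length(p))])))
    sc[interior] <- sc[interior] + 1
  }
  sc
}

# Local clustering by direct triple enumeration over the adjacency lists.
oracle_local_clustering <- function(g) {
  adj <- oracle_adjacency(g)
  vapply(names(adj), function(v) {
    nb <- adj[[v]]
    d <- length(nb)
    if (d < 2) return(0)
    links <- 0
    prs <- utils::combn(nb, 2)
    for (j in seq_len(ncol(prs))) {
      if (prs[2, j] %in% adj[[prs[1, j]]]) links <- links + 1
    }
    links / (d * (d - 1) / 2)
  }, numeric(1))
}

# Connected components by union-find over the edge list.
oracle_components <- function(g) {
  nm <- igraph::V(g)$name
  parent <- stats::setNames(nm, nm)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    ra <- find(el[r, 1]); rb <- find(el[r, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nm, find, "")
  comps <- lapply(split(nm, roots), sort)
  unname(comps[order(-vapply(comps, length, 1L),
                     vapply(comps, `[`, "", 1L))])
}

# Exact upper-tail hypergeometric p by enumerating every possible query
# draw of size n from a background of size N (viable for N <= 12).
oracle_fisher_p <- function(k, K, N, n) {
  bg <- seq_len(N)
  term <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- vapply(seq_len(ncol(draws)), function(j)
    sum(draws[, j] %in% term), numeric(1))
  mean(hits >= k)
}

# Closed-form simple linear regression (log10-log10) for power-law checks.
oracle_loglog_slope <- function(k, nk) {
  x <- log10(k); y <- log10(nk)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}
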