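#' Betweenness scores for bottleneck detection
#'
#' Unnormalized shortest-path betweenness over unordered node pairs. In the
#' default `"fractional"` mode each pair (s, t) distributes one unit of
#' credit among its shortest paths, so an interior node v receives
#' sigma_st(v) / sigma_st (Brandes accumulation; the convention of the
#' standard network-analysis tools). The `"strict"` mode instead awards a
#' full unit whenever v lies on any shortest s-t path, for sensitivity
#' analysis of the bottleneck ranking.
#'
#' @param network An interaction network.
#' @param mode `"fractional"` or `"strict"`.
#' @return Named numeric vector of scores (class `betweenness_scores`).
#' @export
betweenness_scores <- function(network, mode = c("fractional", "strict")) {
  assert_network(network)
  mode <- match.arg(mode)
  if (mode == "fractional") {
    sc <- igraph::betweenness(network, directed = FALSE, weights = NA)
    names(sc) <- node_names(network)
  } else {
    d <- igraph::distances(network)
    nm <- node_names(network)
    n <- length(nm)
    sc <- stats::setNames(numeric(n), nm)
    for (vi in seq_len(n)) {
      thru <- outer(d[, vi], d[vi, ], `+`) == d & is.finite(d)
      thru[vi, ] <- FALSE; thru[, vi] <- FALSE
      diag(thru) <- FALSE
      sc[vi] <- sum(thru[upper.tri(thru)])
    }
  }
  structure(sc, class = c("betweenness_scores", "numeric"))
}

#' Rank bottleneck proteins by betweenness
#'
#' Orders nodes by descending betweenness (ties broken lexicographically and
#' flagged), takes the top `k` after expanding ties at the cutoff score, and
#' intersects with a hub set if one is supplied.
#'
#' @param scores Scores from [betweenness_scores()] (or any named vector).
#' @param k Number of top bottlenecks to report.
#' @param hubs Optional character vector of hub symbols.
#' @return Object of class `bottleneck_report`: list with `ranked` (data
#'   frame `node`, `score`, `tied`), `top_k`, `hub_bottlenecks`.
#' @export
top_bottlenecks <- function(scores, k = 10, hubs = NULL) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k > length(scores)) {
    stop("`k` exceeds the number of scored nodes", call. = FALSE)
  }
  ord <- order(-scores, names(scores))
  ranked <- data.frame(node = names(scores)[ord],
                       score = unname(scores[ord]),
                       stringsAsFactors = FALSE)
  ranked$tied <- duplicated(ranked$score) | duplicated(ranked$score,
                                                       fromLast = TRUE)
  cutoff <- ranked$score[k]
  top <- ranked$node[ranked$score >= cutoff]
  structure(list(ranked = ranked, top_k = top,
                 hub_bottlenecks = intersect(top, hubs %||% character())),
            class = "bottleneck_report")
}

#' Pairwise shortest-path lengths among a node set
#'
#' Reports the shortest-path length for every unordered pair from a set of
#' proteins (e.g. the top bottlenecks), flagging pairs further apart than
#' three steps; a disconnected pair is recorded as unreachable, not an
#' error.
#'
#' @param network An interaction network.
#' @param nodes Character vector of node symbols (all must be present).
#' @return Data frame with columns `node_a`, `node_b`, `length`,
#'   `reachable`, `within_three`.
#' @export
pairwise_bottleneck_paths <- function(network, nodes) {
  assert_network(network)
  nodes <- sort(unique(nodes))
  missing <- setdiff(nodes, node_names(network))
  if (length(missing)) {
    stop("nodes not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(nodes) < 2) {
    return(data.frame(node_a = character(), node_b = character(),
                      length = numeric(), reachable = logical(),
                      within_three = logical(), stringsAsFactors = FALSE))
  }
  d <- igraph::distances(network, v = nodes, to = nodes)
  pairs <- utils::combn(nodes, 2)
  len <- d[cbind(match(pairs[1, ], nodes), match(pairs[2, ], nodes))]
  reachable <- is.finite(len)
  data.frame(node_a = pairs[1, ], node_b = pairs[2, ],
             length = ifelse(reachable, len, NA_real_),
             reachable = reachable,
             within_three = reachable & len <= 3,
             stringsAsFactors = FALSE)
}
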