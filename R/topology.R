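#' Node degree distribution
#'
#' Counts the number of nodes N(k) with each degree k, including zero-degree
#' nodes under k = 0. P(k) = N(k)/N is obtained by dividing by the total
#' node count.
#'
#' @param network An interaction network.
#' @return Object of class `degree_distribution`: list with `counts`
#'   (named integer vector, names are degrees) and `n_total`.
#' @export
degree_distribution <- function(network) {
  assert_network(network)
  d <- igraph::degree(network)
  tab <- table(d)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(counts = counts, n_total = igraph::vcount(network)),
            class = "degree_distribution")
}

as_dd <- function(dd) {
  if (inherits(dd, "degree_distribution")) return(dd)
  if (is.numeric(dd) && !is.null(names(dd))) {
    return(structure(list(counts = dd, n_total = sum(dd)),
                     class = "degree_distribution"))
  }
  if (is.data.frame(dd) && all(c("k", "n_k") %in% names(dd))) {
    return(structure(list(counts = stats::setNames(dd$n_k, dd$k),
                          n_total = sum(dd$n_k)),
                     class = "degree_distribution"))
  }
  stop("cannot interpret `dd` as a degree distribution", call. = FALSE)
}

#' Fit a power law to the degree distribution by log-log least squares
#'
#' Ordinary least squares of log10 N(k) on log10 k over degrees k >= 1 with
#' N(k) > 0 (no binning). The degree exponent gamma is the negated slope;
#' the prefactor is 10^intercept, so the fitted relation is
#' N(k) = prefactor * k^(-gamma).
#'
#' @param dd A `degree_distribution`, a named numeric vector of counts
#'   (names are degrees), or a data frame with columns `k` and `n_k`.
#' @return Object of class `power_law_fit`: list with `gamma`, `prefactor`,
#'   `r_squared`, and `n_points` used in the regression.
#' @examples
#' dd <- stats::setNames(100 * (1:20)^-2, 1:20)
#' fit_power_law(dd)$gamma  # 2 to machine precision
#' @export
fit_power_law <- function(dd) {
  dd <- as_dd(dd)
  k <- as.numeric(names(dd$counts))
  nk <- as.numeric(dd$counts)
  keep <- k >= 1 & nk > 0
  k <- k[keep]; nk <- nk[keep]
  if (length(k) < 3) {
    stop("power-law fit needs >= 3 distinct degrees with k >= 1 and N(k) > 0",
         call. = FALSE)
  }
  fit <- stats::lm(log10(nk) ~ log10(k))
  y <- log10(nk)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(gamma = -unname(stats::coef(fit)[2]),
                 prefactor = 10^unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = length(k)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: N(k) = %.4g * k^-%.3f (R^2 = %.3f, %d points)\n",
              x$prefactor, x$gamma, x$r_squared, x$n_points))
  invisible(x)
}

#' Local clustering coefficient of one node
#'
#' Ratio of the number of edges among the node's neighbours to the maximum
#' possible, d(d-1)/2. Nodes with fewer than two neighbours are assigned 0.
#'
#' @param network An interaction network.
#' @param node Node symbol.
#' @return A single value in \[0, 1\].
#' @export
local_clustering <- function(network, node) {
  assert_network(network)
  if (!node %in% node_names(network)) {
    stop(sprintf("node '%s' not in network", node), call. = FALSE)
  }
  val <- igraph::transitivity(network, type = "local", vids = node,
                              isolates = "zero")
  unname(val)
}

#' Global (network-average) clustering coefficient
#'
#' Arithmetic mean of the local clustering coefficients over all nodes,
#' counting zero-degree and degree-1 nodes as 0.
#'
#' @param network A non-empty interaction network.
#' @return Object of class `clustering_report`: list with `per_node` (named
#'   vector) and `global`.
#' @export
global_clustering <- function(network) {
  assert_network(network)
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  per <- igraph::transitivity(network, type = "local", isolates = "zero")
  names(per) <- node_names(network)
  structure(list(per_node = per, global = mean(per)),
            class = "clustering_report")
}

#' Shortest-path length statistics
#'
#' Breadth-first shortest paths over all unordered reachable node pairs;
#' disconnected pairs are excluded rather than assigned infinite length, so
#' the mean is finite on graphs with multiple components.
#'
#' @param network A network with at least one edge.
#' @return Object of class `path_stats`: list with `histogram` (named count
#'   vector, names are path lengths), `mean`, `max`, and `n_pairs`.
#' @export
path_length_stats <- function(network) {
  assert_network(network)
  if (igraph::ecount(network) == 0) {
    stop("path statistics need at least one edge", call. = FALSE)
  }
  d <- igraph::distances(network)
  len <- d[upper.tri(d)]
  len <- len[is.finite(len) & len > 0]
  tab <- table(len)
  hist <- stats::setNames(as.integer(tab), names(tab))
  structure(list(histogram = hist,
                 mean = sum(as.numeric(names(hist)) * hist) / sum(hist),
                 max = max(as.numeric(names(hist))),
                 n_pairs = sum(hist)),
            class = "path_stats")
}

#' Connected components and isolated nodes
#'
#' @param network An interaction network.
#' @return List with `components` (list of sorted node-name vectors, largest
#'   component first), `sizes`, and `isolates` (zero-degree nodes).
#' @export
network_components <- function(network) {
  assert_network(network)
  comp <- igraph::components(network)
  nm <- node_names(network)
  groups <- split(nm, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, 1L),
               vapply(groups, `[`, "", 1L))
  groups <- unname(groups[ord])
  list(components = groups,
       sizes = vapply(groups, length, 1L),
       isolates = sort(nm[igraph::degree(network) == 0]))
}

#' Identify hub proteins from the degree sequence
#'
#' Two rules are available. `"top_fraction"` keeps the nodes whose degree
#' reaches the degree of the rank-`floor(param * n)` node (ties at the
#' threshold are included, so every hub degree is at least every non-hub
#' degree). `"degree_gap"` (the default) scans the descending degree
#' sequence within the top decile for the largest consecutive drop: nodes
#' above that gap are the hubs, and nodes between the primary gap and the
#' largest later gap form a second tier. On a two-tier degree sequence the
#' gap rule recovers both tiers without a hand-picked fraction.
#'
#' @param network A non-empty interaction network.
#' @param method `"degree_gap"` or `"top_fraction"`.
#' @param param For `"top_fraction"`, the fraction in (0, 1); ignored by
#'   `"degree_gap"`.
#' @return Object of class `hub_report`: list with `ranked` (data frame
#'   `node`, `degree`, descending), `hubs`, `second_tier`, `method`.
#' @export
identify_hubs <- function(network, method = c("degree_gap", "top_fraction"),
                          param = 0.2) {
  assert_network(network)
  method <- match.arg(method)
  d <- igraph::degree(network)
  if (length(d) == 0) stop("empty network", call. = FALSE)
  ord <- order(-d, names(d))
  ranked <- data.frame(node = names(d)[ord], degree = unname(d[ord]),
                       stringsAsFactors = FALSE)
  n <- nrow(ranked)
  if (method == "top_fraction") {
    if (!is.numeric(param) || param <= 0 || param >= 1) {
      stop("`param` must lie in (0, 1) for top_fraction", call. = FALSE)
    }
    k <- max(1L, floor(param * n))
    thr <- ranked$degree[k]
    hubs <- ranked$node[ranked$degree >= thr]
    second <- character()
  } else {
    m <- min(n, max(2L, ceiling(0.1 * n)))
    hubs <- ranked$node[1]
    second <- character()
    if (m >= 2) {
      gaps <- ranked$degree[1:(m - 1)] - ranked$degree[2:m]
      # primary cut: largest drop; ties resolved toward the deeper position
      # so a repeated gap size yields the more inclusive hub set
      primary <- max(which(gaps == max(gaps)))
      hubs <- ranked$node[seq_len(primary)]
      rest <- if (primary + 1 <= m - 1) gaps[(primary + 1):(m - 1)] else numeric()
      if (length(rest) > 0 && max(rest) > 0) {
        secondary <- primary + max(which(rest == max(rest)))
        second <- ranked$node[(primary + 1):secondary]
      }
    }
  }
  structure(list(ranked = ranked, hubs = hubs, second_tier = second,
                 method = method, param = param),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hubs (%s): %s\n", x$method, paste(x$hubs, collapse = ", ")))
  if (length(x$second_tier)) {
    cat("Second tier:", paste(x$second_tier, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Share of all network connections held by a set of degrees
#'
#' Percentage of the network's edges accounted for by the given node
#' degrees: `100 * sum(degrees) / n_edges`. Used to express how much of the
#' total connectivity the hub tiers carry.
#'
#' @param degrees Vector of node degrees.
#' @param n_edges Total number of edges in the network.
#' @return Percentage (unrounded).
#' @examples
#' degree_share(c(134, 110, 96, 77), 1943)  # ~21.5
#' @export
degree_share <- function(degrees, n_edges) {
  if (n_edges <= 0) stop("`n_edges` must be positive", call. = FALSE)
  100 * sum(degrees) / n_edges
}
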