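#' Parameters for degree-preserving edge rewiring
#'
#' @param swaps_per_edge Target number of successful swaps per edge (the
#'   rewire aims for `ceiling(swaps_per_edge * |E|)` successes; 10 is a
#'   standard mixing heuristic).
#' @param max_attempts_factor Give up, with a warning, after this many
#'   failed proposals per targeted success.
#' @param seed Integer RNG seed for reproducibility.
#' @return Object of class `rewire_params`.
#' @export
rewire_params <- function(swaps_per_edge = 10, max_attempts_factor = 100,
                          seed = 1L) {
  if (swaps_per_edge <= 0) stop("`swaps_per_edge` must be > 0", call. = FALSE)
  structure(list(swaps_per_edge = swaps_per_edge,
                 max_attempts_factor = max_attempts_factor,
                 seed = as.integer(seed)),
            class = "rewire_params")
}

#' Degree-preserving randomization by edge swaps
#'
#' Repeatedly selects two edges (u,v) and (s,t) with all four endpoints
#' pairwise distinct and with (u,t) and (s,v) absent from the graph, then
#' replaces the pair with (u,t) and (s,v). Every node keeps its exact
#' degree, no self-loops or duplicate edges can arise, and the edge count
#' is conserved. The second edge's orientation is randomized so all valid
#' swaps are reachable. Stops after the target number of successful swaps,
#' or with a warning once the attempt budget is exhausted (e.g. a triangle
#' admits no valid swap and is returned unchanged). Edge confidence and
#' evidence attributes are dropped: a rewired graph is a topological null,
#' not a curated record set.
#'
#' @param network A network with at least 2 edges (smaller graphs are
#'   returned unchanged with a warning).
#' @param params A [rewire_params()] object.
#' @return A rewired network with identical vertex set and degree sequence.
#' @export
rewire_degree_preserving <- function(network, params = rewire_params()) {
  assert_network(network)
  nm <- node_names(network)
  el <- igraph::as_edgelist(network, names = FALSE)
  m <- nrow(el)
  if (m < 2) {
    warning("fewer than 2 edges: returning the network unchanged")
    return(strip_edge_attrs(network))
  }
  target <- ceiling(params$swaps_per_edge * m)
  budget <- params$max_attempts_factor * target
  withr::with_seed(params$seed, {
    adj <- lapply(seq_along(nm), function(i) integer())
    for (r in seq_len(m)) {
      adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
      adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
    }
    succ <- 0L
    att <- 0L
    while (succ < target && att < budget) {
      att <- att + 1L
      pick <- sample.int(m, 2L)
      u <- el[pick[1], 1]; v <- el[pick[1], 2]
      s <- el[pick[2], 1]; t <- el[pick[2], 2]
      if (stats::runif(1) < 0.5) { tmp <- s; s <- t; t <- tmp }
      if (u == s || u == t || v == s || v == t) next
      if (t %in% adj[[u]] || v %in% adj[[s]]) next
      adj[[u]] <- c(setdiff(adj[[u]], v), t)
      adj[[v]] <- c(setdiff(adj[[v]], u), s)
      adj[[s]] <- c(setdiff(adj[[s]], t), v)
      adj[[t]] <- c(setdiff(adj[[t]], s), u)
      el[pick[1], ] <- c(u, t)
      el[pick[2], ] <- c(s, v)
      succ <- succ + 1L
    }
  })
  if (succ < target) {
    warning(sprintf(
      "rewire stopped after %d of %d target swaps (attempt budget reached)",
      succ, target))
  }
  sf <- igraph::vertex_attr(network, "subfamily")
  sfmap <- if (is.null(sf)) NULL else stats::setNames(sf, nm)
  graph_from_pairs(nm[el[, 1]], nm[el[, 2]], vertices = nm, subfamily = sfmap)
}

strip_edge_attrs <- function(network) {
  nm <- node_names(network)
  el <- igraph::as_edgelist(network)
  sf <- igraph::vertex_attr(network, "subfamily")
  sfmap <- if (is.null(sf)) NULL else stats::setNames(sf, nm)
  graph_from_pairs(el[, 1], el[, 2], vertices = nm, subfamily = sfmap)
}

#' Null ensemble of clustering coefficients from rewired replicates
#'
#' Generates `n_reps` independent degree-preserving randomizations (seeded
#' as `params$seed + replicate index`), computes the global clustering
#' coefficient of each, and summarizes the ensemble with its mean and
#' sample (n - 1) standard deviation.
#'
#' @param network An interaction network.
#' @param n_reps Number of randomized replicates (>= 2).
#' @param params A [rewire_params()] object.
#' @param statistic Function mapping a network to one number; defaults to
#'   the global clustering coefficient.
#' @return Object of class `null_ensemble`: list with `n_reps`, `values`,
#'   `mean`, `sd`.
#' @export
null_clustering_ensemble <- function(network, n_reps = 100,
                                     params = rewire_params(),
                                     statistic = function(g)
                                       global_clustering(g)$global) {
  if (n_reps < 2) stop("`n_reps` must be >= 2", call. = FALSE)
  values <- vapply(seq_len(n_reps), function(r) {
    p <- params
    p$seed <- params$seed + r
    g <- suppressWarnings(rewire_degree_preserving(network, p))
    statistic(g)
  }, numeric(1))
  structure(list(n_reps = n_reps, values = values, mean = mean(values),
                 sd = stats::sd(values)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %d replicates, mean = %.4f, sd = %.4f\n",
              x$n_reps, x$mean, x$sd))
  invisible(x)
}

#' One-sample Z test of an observed statistic against a null ensemble
#'
#' Reports the deviation of the observed value from the null mean in two
#' conventions: `z_sd`, in units of the null standard deviation, and
#' `z_se`, in units of the standard error `sd / sqrt(n)`. The two-sided p
#' value comes from the standard normal tail of `z_se`. The sign follows
#' the `observed - null` convention, so strong excess clustering gives a
#' large positive z. With a degenerate ensemble (sd = 0) the z values are
#' +/-Inf when the observed value differs from the null mean, 0 otherwise.
#'
#' @param observed The observed statistic.
#' @param ensemble A [null_clustering_ensemble()] result, or a list with
#'   `mean`, `sd`, `n_reps`.
#' @return Object of class `z_test`: list with `z_sd`, `z_se`,
#'   `p_two_sided`, `observed`, `null_mean`, `null_sd`, `n`.
#' @export
one_sample_z <- function(observed, ensemble) {
  mu <- ensemble$mean
  s <- ensemble$sd
  n <- ensemble$n_reps %||% length(ensemble$values)
  diff <- observed - mu
  if (s == 0) {
    z_sd <- if (diff == 0) 0 else sign(diff) * Inf
    z_se <- z_sd
  } else {
    z_sd <- diff / s
    z_se <- diff / (s / sqrt(n))
  }
  p <- if (is.infinite(z_se)) 0 else 2 * stats::pnorm(-abs(z_se))
  structure(list(z_sd = z_sd, z_se = z_se, p_two_sided = p,
                 observed = observed, null_mean = mu, null_sd = s, n = n),
            class = "z_test")
}

#' @export
print.z_test <- function(x, ...) {
  cat(sprintf(
    "One-sample Z: observed %.4g vs null %.4g +/- %.4g (n = %d)\n",
    x$observed, x$null_mean, x$null_sd, x$n))
  cat(sprintf("  z (SE convention) = %.2f, z (SD convention) = %.2f, p = %.3g\n",
              x$z_se, x$z_sd, x$p_two_sided))
  invisible(x)
}

#' MCODE on a degree-preserving randomized control graph
#'
#' Rewires the network once and runs the same complex-detection procedure
#' with the same parameters, providing the randomized-graph control for the
#' observed clusters.
#'
#' @param network An interaction network.
#' @param rewire A [rewire_params()] object.
#' @param params An [mcode_params()] object.
#' @return An `mcode_clusters` object from the rewired graph.
#' @export
randomized_mcode_control <- function(network, rewire = rewire_params(),
                                     params = mcode_params()) {
  g <- suppressWarnings(rewire_degree_preserving(network, rewire))
  mcode(g, params)
}
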