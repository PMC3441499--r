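#' Build a subfamily subnetwork from seed GTPases
#'
#' Keeps every record with at least one endpoint among the seed symbols, so
#' the subnetwork consists of the seeds plus their first neighbours and all
#' seed-incident edges; an edge between two non-seed proteins is excluded.
#' Seeds with no matching records remain as isolated nodes.
#'
#' @param records Interaction records.
#' @param seeds Non-empty character vector of seed GTPase symbols.
#' @param label Subfamily label (e.g. "RHO").
#' @return Object of class `subfamily_network`: list with `subfamily`,
#'   `seeds`, `network` (igraph), `members`.
#' @export
subfamily_network <- function(records, seeds, label) {
  if (length(seeds) == 0) stop("`seeds` must be non-empty", call. = FALSE)
  seeds <- sort(unique(canonical_symbols(seeds)))
  a <- canonical_symbols(records$protein_a)
  b <- canonical_symbols(records$protein_b)
  keep <- (a %in% seeds | b %in% seeds) & a != b
  sfmap <- stats::setNames(rep(label, length(seeds)), seeds)
  g <- if (any(keep)) {
    cp <- canonical_pairs(a[keep], b[keep])
    first <- !duplicated(cp$key)
    graph_from_pairs(a[keep][first], b[keep][first], vertices = seeds,
                     confidence = records$confidence[keep][first],
                     subfamily = sfmap)
  } else {
    graph_from_pairs(character(), character(), vertices = seeds,
                     subfamily = sfmap)
  }
  structure(list(subfamily = label, seeds = seeds, network = g,
                 members = node_names(g)),
            class = "subfamily_network")
}

#' Proteins shared across subfamily networks
#'
#' Cross-checks a set of subfamily networks for mutually occurring
#' proteins: every protein present in at least two subfamily networks is
#' reported, grouped by how many networks it appears in and by the exact
#' label combination. GTPase seeds can themselves appear as members of
#' another subfamily's network; set `include_seeds = FALSE` to restrict the
#' report to non-seed partner proteins.
#'
#' @param subnetworks List of [subfamily_network()] objects (>= 2).
#' @param include_seeds Count seed GTPases as shareable members.
#' @return Object of class `overlap_report`: list with `membership`
#'   (named list protein -> sorted label vector), `by_count` (list indexed
#'   by "2", "3", ... of protein vectors), `by_combination` (named counts,
#'   combination labels joined with "+"), `n_shared`.
#' @export
shared_proteins <- function(subnetworks, include_seeds = TRUE) {
  if (length(subnetworks) < 2) {
    stop("need at least 2 subfamily networks", call. = FALSE)
  }
  all_seeds <- unique(unlist(lapply(subnetworks, `[[`, "seeds")))
  pairs <- do.call(rbind, lapply(subnetworks, function(sn) {
    data.frame(protein = sn$members, label = sn$subfamily,
               stringsAsFactors = FALSE)
  }))
  membership <- lapply(split(pairs$label, pairs$protein),
                       function(x) sort(unique(x)))
  if (!include_seeds) {
    membership <- membership[!names(membership) %in% all_seeds]
  }
  shared <- membership[vapply(membership, length, 1L) >= 2]
  combo <- vapply(shared, paste, "", collapse = "+")
  by_comb <- if (length(combo)) table(combo) else table(character())
  counts <- vapply(shared, length, 1L)
  by_count <- lapply(split(names(shared), counts), sort)
  structure(list(membership = membership, by_count = by_count,
                 by_combination = stats::setNames(as.integer(by_comb),
                                                  names(by_comb)),
                 n_shared = length(shared)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%d proteins shared by >= 2 subfamily networks\n", x$n_shared))
  for (k in names(x$by_count)) {
    cat(sprintf("  in %s networks: %d\n", k, length(x$by_count[[k]])))
  }
  invisible(x)
}

#' First (immediate) neighbours of a protein
#'
#' @param network An interaction network.
#' @param protein Node symbol (must be present).
#' @return Sorted character vector of adjacent symbols.
#' @export
first_neighbors_of <- function(network, protein) {
  assert_network(network)
  if (!protein %in% node_names(network)) {
    stop(sprintf("protein '%s' not in network", protein), call. = FALSE)
  }
  sort(names(igraph::neighbors(network, protein)))
}

#' Interaction coverage of the curated seed lists
#'
#' For each subfamily, how many of the searched GTPases appear in at least
#' one interaction record.
#'
#' @param seed_table Named list: subfamily label -> character vector of
#'   searched symbols.
#' @param records Interaction records.
#' @return Data frame with columns `subfamily`, `n_searched`,
#'   `n_with_interactions`.
#' @export
coverage_stats <- function(seed_table, records) {
  touched <- unique(c(canonical_symbols(records$protein_a),
                      canonical_symbols(records$protein_b)))
  rows <- lapply(names(seed_table), function(lab) {
    seeds <- unique(canonical_symbols(seed_table[[lab]]))
    data.frame(subfamily = lab, n_searched = length(seeds),
               n_with_interactions = sum(seeds %in% touched),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
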