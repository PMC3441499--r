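#' Configuration for the full network-analysis pipeline
#'
#' @param edges Interaction records (data frame) or a path to an edge
#'   table.
#' @param annotations Annotation data frame, or path, or `NULL`.
#' @param format Edge-table format when `edges` is a path.
#' @param min_confidence Confidence threshold (inclusive).
#' @param exclude Optional two-column blacklist of pairs to drop.
#' @param hub_method,hub_param Passed to [identify_hubs()].
#' @param bottleneck_k Number of top bottlenecks to report.
#' @param mcode_parameters An [mcode_params()] object.
#' @param n_reps Null-ensemble replicates.
#' @param swaps_per_edge Rewiring intensity for the null model.
#' @param rng_seed Seed controlling every stochastic stage.
#' @param out_dir Optional directory; when set, tables and a JSON bundle
#'   are written there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(edges, annotations = NULL,
                            format = c("tsv", "sif"), min_confidence = 0.4,
                            exclude = NULL, hub_method = "degree_gap",
                            hub_param = 0.2, bottleneck_k = 10,
                            mcode_parameters = mcode_params(), n_reps = 100,
                            swaps_per_edge = 10, rng_seed = 1L,
                            out_dir = NULL) {
  structure(list(edges = edges, annotations = annotations,
                 format = match.arg(format),
                 min_confidence = min_confidence, exclude = exclude,
                 hub_method = hub_method, hub_param = hub_param,
                 bottleneck_k = bottleneck_k,
                 mcode_parameters = mcode_parameters, n_reps = n_reps,
                 swaps_per_edge = swaps_per_edge,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full interaction-network analysis pipeline
#'
#' Stages, in order: ingest and confidence-filter the records, build the
#' merged undirected simple network (dropping any blacklisted pairs),
#' topology metrics (degree distribution, power-law fit, clustering,
#' shortest paths, components, hub tiers, degree shares), betweenness
#' bottlenecks, MCODE-style complex detection, the degree-preserving null
#' ensemble with a one-sample Z test of the observed clustering, a
#' randomized-graph MCODE control, and subfamily cross-talk overlap (when
#' annotations provide seed subfamilies). Every stochastic stage is seeded
#' from `rng_seed`, so the bundle is reproducible bit for bit.
#'
#' @param config A [pipeline_config()] object.
#' @return Object of class `report_bundle`: list with `summary`, `hubs`,
#'   `bottlenecks`, `clusters`, `cluster_table`, `control_clusters`,
#'   `null`, `z_test`, `crosstalk`, `coverage`, `confidence`, `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  records <- if (is.character(config$edges)) {
    parse_edge_table(config$edges, config$format)
  } else {
    config$edges
  }
  anno <- config$annotations
  if (is.character(anno)) anno <- read_annotation_table(anno)
  records <- filter_by_confidence(records, config$min_confidence)
  if (nrow(records) == 0) stop("no records pass the confidence filter",
                               call. = FALSE)
  network <- build_network(records, anno)
  network <- exclude_edges(network, config$exclude)

  conf_sum <- confidence_summary(records)
  dd <- degree_distribution(network)
  fit <- fit_power_law(dd)
  clus <- global_clustering(network)
  paths <- path_length_stats(network)
  comps <- network_components(network)
  hubs <- identify_hubs(network, config$hub_method, config$hub_param)
  deg <- igraph::degree(network)
  n_edges <- igraph::ecount(network)
  share_hubs <- degree_share(deg[hubs$hubs], n_edges)
  share_second <- if (length(hubs$second_tier)) {
    degree_share(deg[hubs$second_tier], n_edges)
  } else 0
  bt <- betweenness_scores(network)
  bottle <- top_bottlenecks(bt, k = min(config$bottleneck_k,
                                        igraph::vcount(network)),
                            hubs = hubs$hubs)
  clusters <- mcode(network, config$mcode_parameters)
  rw <- rewire_params(swaps_per_edge = config$swaps_per_edge,
                      seed = config$rng_seed)
  null_ens <- null_clustering_ensemble(network, n_reps = config$n_reps,
                                       params = rw)
  ztest <- one_sample_z(clus$global, null_ens)
  control_rw <- rewire_params(swaps_per_edge = config$swaps_per_edge,
                              seed = config$rng_seed + 10000L)
  control <- randomized_mcode_control(network, control_rw,
                                      config$mcode_parameters)

  crosstalk <- NULL
  coverage <- NULL
  if (!is.null(anno) && nrow(anno) > 0) {
    seed_table <- split(canonical_symbols(anno$symbol), anno$subfamily)
    seed_table <- seed_table[setdiff(names(seed_table), "OTHER")]
    if (length(seed_table) >= 2) {
      subnets <- lapply(names(seed_table), function(lab) {
        subfamily_network(records, seed_table[[lab]], lab)
      })
      crosstalk <- shared_proteins(subnets)
      coverage <- coverage_stats(seed_table, records)
    }
  }

  bundle <- structure(list(
    summary = list(
      n_nodes = igraph::vcount(network), n_edges = n_edges,
      n_components = length(comps$components),
      n_isolates = length(comps$isolates),
      gamma = fit$gamma, r_squared = fit$r_squared,
      global_clustering = clus$global, mean_path_length = paths$mean,
      hub_degree_share_pct = share_hubs,
      second_tier_degree_share_pct = share_second,
      combined_degree_share_pct = share_hubs + share_second),
    degree_distribution = dd, power_law = fit, path_stats = paths,
    components = comps, hubs = hubs, bottlenecks = bottle,
    clusters = clusters, cluster_table = render_cluster_table(clusters),
    control_clusters = control, null = null_ens, z_test = ztest,
    crosstalk = crosstalk, coverage = coverage, confidence = conf_sum,
    network = network,
    config = config), class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Render an MCODE cluster list as a publication-style table
#'
#' One row per cluster: rank, score rendered to one decimal (half-up),
#' node and edge counts, the seed node, and the comma-joined sorted member
#' symbols.
#'
#' @param clusters An `mcode_clusters` object (possibly empty).
#' @return Data frame with columns `rank`, `score`, `nodes`, `edges`,
#'   `seed`, `members`.
#' @export
render_cluster_table <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(rank = integer(), score = character(),
                      nodes = integer(), edges = integer(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rank = seq_along(clusters),
    score = sprintf("%.1f", round_half_up(
      vapply(clusters, `[[`, 1, "score"), 1)),
    nodes = vapply(clusters, `[[`, 1L, "n_members"),
    edges = vapply(clusters, `[[`, 1L, "n_edges"),
    seed = vapply(clusters, `[[`, "", "seed"),
    members = vapply(clusters, function(cl) paste(sort(cl$members),
                                                  collapse = ", "), ""),
    stringsAsFactors = FALSE)
}

# Serialize the bundle deterministically (used for the reproducibility
# contract and by write_bundle).
bundle_json <- function(bundle) {
  x <- bundle
  x$network <- NULL  # igraph objects carry environments; edges are exported
  x$config$edges <- NULL
  x$config$annotations <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                   null = "null")
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  el <- igraph::as_edgelist(bundle$network)
  write.table(data.frame(protein_a = el[, 1], protein_b = el[, 2]),
              file.path(out_dir, "network_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$cluster_table, file.path(out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$bottlenecks$ranked,
              file.path(out_dir, "bottlenecks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$hubs$ranked, file.path(out_dir, "degree_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle_json(bundle), file.path(out_dir, "bundle.json"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  s <- x$summary
  cat("Interaction network analysis\n")
  cat(sprintf("  nodes %d, edges %d, components %d (%d isolates)\n",
              s$n_nodes, s$n_edges, s$n_components, s$n_isolates))
  cat(sprintf("  degree exponent %.2f (R^2 %.2f)\n", s$gamma, s$r_squared))
  cat(sprintf("  global clustering %.3f vs null %.3f +/- %.3f (z = %.1f)\n",
              s$global_clustering, x$null$mean, x$null$sd, x$z_test$z_se))
  cat(sprintf("  mean path length %.2f\n", s$mean_path_length))
  cat(sprintf("  hubs: %s (%.1f%% of connections)\n",
              paste(x$hubs$hubs, collapse = ", "),
              round_half_up(s$hub_degree_share_pct, 1)))
  cat(sprintf("  clusters: %d (control: %d)\n", length(x$clusters),
              length(x$control_clusters)))
  invisible(x)
}
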