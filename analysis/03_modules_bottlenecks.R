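#!/usr/bin/env Rscript
# Stage 3: betweenness bottlenecks and MCODE-style complex detection.

suppressMessages(library(gtpnet))

records <- filter_by_confidence(parse_edge_table("results/edges.tsv"), 0.4)
anno <- read_annotation_table("results/annotations.tsv")
net <- build_network(records, anno)

hubs <- identify_hubs(net, "degree_gap")
sc <- betweenness_scores(net)
bottle <- top_bottlenecks(sc, k = 10, hubs = hubs$hubs)
tab <- bottle$ranked[bottle$ranked$node %in% bottle$top_k, ]
tab$is_hub <- tab$node %in% hubs$hubs
write.table(tab, "results/bottlenecks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top bottlenecks:", paste(head(tab$node, 10), collapse = ", "), "\n")
cat("hub-bottlenecks:", paste(bottle$hub_bottlenecks, collapse = ", "), "\n")

paths <- pairwise_bottleneck_paths(net, bottle$top_k)
cat(sprintf("bottleneck pairs within three steps: %d of %d\n",
            sum(paths$within_three), nrow(paths)))

clusters <- mcode(net, mcode_params(degree_cutoff = 2,
                                    node_score_cutoff = 0.2, k_core = 3,
                                    haircut = TRUE))
cluster_tab <- render_cluster_table(clusters)
write.table(cluster_tab, "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(cluster_tab[, c("rank", "score", "nodes", "edges", "seed")])
cat(sprintf("%d proteins of %d sit inside clusters\n",
            length(unlist(lapply(clusters, `[[`, "members"))),
            igraph::vcount(net)))
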