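#!/usr/bin/env Rscript
# Stage 5: cross-talk between the subfamily networks (shared proteins and
# their first neighbors), seed-list coverage, and a worked
# over-representation test against a user-suppliable annotation table.

suppressMessages(library(gtpnet))

records <- filter_by_confidence(parse_edge_table("results/edges.tsv"), 0.4)
anno <- read_annotation_table("results/annotations.tsv")
seed_table <- split(anno$symbol, anno$subfamily)
seed_table <- seed_table[setdiff(names(seed_table), "OTHER")]

subnets <- lapply(names(seed_table), function(lab)
  subfamily_network(records, seed_table[[lab]], lab))
ov <- shared_proteins(subnets)
print(ov)
comb <- data.frame(combination = names(ov$by_combination),
                   n = ov$by_combination)
write.table(comb, "results/shared_by_combination.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# first neighbors of proteins present in >= 3 subfamily networks
net <- build_network(records, anno)
multi <- unlist(ov$by_count[as.integer(names(ov$by_count)) >= 3],
                use.names = FALSE)
nbr <- data.frame(
  protein = multi,
  networks = vapply(ov$membership[multi], paste, "", collapse = "+"),
  first_neighbors = vapply(multi, function(p)
    paste(first_neighbors_of(net, p), collapse = ", "), ""))
write.table(nbr, "results/multi_network_neighbors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cov <- coverage_stats(seed_table, records)
write.table(cov, "results/coverage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(cov)

# over-representation demo: an annotation table derived from the fixture's
# subfamily neighborhoods (stand-in for pathway/domain tables)
terms <- lapply(subnets, function(sn) setdiff(sn$members, sn$seeds))
names(terms) <- paste0("neighbors_of_", vapply(subnets, `[[`, "", "subfamily"))
query <- unique(unlist(lapply(
  ov$by_count[as.integer(names(ov$by_count)) >= 2], identity)))
enr <- fisher_enrichment(query, terms,
                         background = igraph::V(net)$name)
sig <- filter_significant(enr, alpha = 0.05)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d terms significant at P <= 0.05\n", nrow(sig),
            nrow(enr)))
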