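#' Parse a STRING-style edge table or SIF file into interaction records
#'
#' Reads curated protein-protein interaction records from a tab-separated
#' edge table (columns `protein_a`, `protein_b`, `score`, `evidence`; header
#' optional and auto-detected) or from a SIF file
#' (`nodeA <relation> nodeB [nodeC ...]`, fan-out rows expanded to pairwise
#' edges). Gene symbols are uppercased and stripped of surrounding
#' whitespace; no alias resolution is attempted. SIF rows carry no
#' confidence, so records parsed from SIF default to confidence 1.0 with the
#' relation string stored as the evidence tag.
#'
#' @param input Path to a file, or a character vector of lines (anything of
#'   length > 1, or containing a newline, is treated as literal text).
#' @param format `"tsv"` or `"sif"`.
#' @return A data frame of interaction records with columns `protein_a`,
#'   `protein_b`, `confidence`, `evidence`, one row per record, input order
#'   preserved.
#' @examples
#' recs <- parse_edge_table(c("RAC1\tPAK1\t0.9\texp", "rac1\tcdc42\t0.5\texp"))
#' recs$protein_b
#' @export
parse_edge_table <- function(input, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- read_input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_records())
  }
  if (format == "tsv") parse_tsv_lines(lines) else parse_sif_lines(lines)
}

read_input_lines <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  unlist(strsplit(as.character(input), "\n", fixed = TRUE), use.names = FALSE)
}

empty_records <- function() {
  data.frame(protein_a = character(), protein_b = character(),
             confidence = numeric(), evidence = character(),
             stringsAsFactors = FALSE)
}

parse_tsv_lines <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  first <- fields[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) {
    start <- 2L  # header row
  }
  if (start > length(fields)) return(empty_records())
  rows <- fields[start:length(fields)]
  line_no <- seq_along(fields)[start:length(fields)]
  n_fld <- lengths(rows)
  bad <- which(n_fld < 3)
  if (length(bad)) {
    stop(sprintf("malformed TSV row at line %d: expected >= 3 tab-separated fields",
                 line_no[bad[1]]), call. = FALSE)
  }
  a <- canonical_symbols(vapply(rows, `[`, "", 1L))
  b <- canonical_symbols(vapply(rows, `[`, "", 2L))
  conf <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  ev <- vapply(rows, function(r) if (length(r) >= 4) r[[4]] else "", "")
  bad <- which(is.na(conf))
  if (length(bad)) {
    stop(sprintf("malformed confidence score at line %d", line_no[bad[1]]),
         call. = FALSE)
  }
  bad <- which(conf < 0 | conf > 1)
  if (length(bad)) {
    stop(sprintf("confidence score outside [0, 1] at line %d (value %g)",
                 line_no[bad[1]], conf[bad[1]]), call. = FALSE)
  }
  bad <- which(!nzchar(a) | !nzchar(b))
  if (length(bad)) {
    stop(sprintf("empty protein symbol at line %d", line_no[bad[1]]),
         call. = FALSE)
  }
  data.frame(protein_a = a, protein_b = b, confidence = conf, evidence = ev,
             stringsAsFactors = FALSE)
}

parse_sif_lines <- function(lines) {
  out_a <- character(); out_b <- character(); out_ev <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) == 1) next  # lone-node declaration: no interaction record
    if (length(tok) == 2) {
      stop(sprintf("malformed SIF row at line %d: relation with no target", i),
           call. = FALSE)
    }
    src <- canonical_symbols(tok[1])
    rel <- tok[2]
    tgt <- canonical_symbols(tok[3:length(tok)])
    if (!nzchar(src) || any(!nzchar(tgt))) {
      stop(sprintf("empty protein symbol at line %d", i), call. = FALSE)
    }
    out_a <- c(out_a, rep(src, length(tgt)))
    out_b <- c(out_b, tgt)
    out_ev <- c(out_ev, rep(rel, length(tgt)))
  }
  data.frame(protein_a = out_a, protein_b = out_b,
             confidence = rep(1.0, length(out_a)), evidence = out_ev,
             stringsAsFactors = FALSE)
}

#' Write interaction records as a canonical edge-list TSV
#'
#' Rows are written with the lexicographically smaller symbol first and
#' sorted, so repeated exports of the same record set are byte-identical.
#'
#' @param records Interaction records (as from [parse_edge_table()]).
#' @param path Output file path.
#' @export
write_edge_table <- function(records, path) {
  cp <- canonical_pairs(records$protein_a, records$protein_b)
  df <- data.frame(protein_a = cp$lo, protein_b = cp$hi,
                   confidence = records$confidence,
                   evidence = records$evidence, stringsAsFactors = FALSE)
  df <- df[order(df$protein_a, df$protein_b, df$confidence), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' @param network An interaction network (igraph).
#' @param path Output file path.
#' @param relation Relation string to use for every edge.
#' @export
write_sif <- function(network, path, relation = "pp") {
  assert_network(network)
  el <- igraph::as_edgelist(network)
  cp <- canonical_pairs(el[, 1], el[, 2])
  ord <- order(cp$lo, cp$hi)
  rows <- paste(cp$lo[ord], relation, cp$hi[ord], sep = "\t")
  isolates <- setdiff(node_names(network), c(el[, 1], el[, 2]))
  writeLines(c(rows, sort(isolates)), path)
  invisible(path)
}

#' Filter interaction records by confidence score
#'
#' Retains records whose confidence is greater than or equal to the
#' threshold (inclusive), so a record scored exactly at the cutoff is kept.
#' The default 0.4 is the STRING "medium confidence" level.
#'
#' @param records Interaction records.
#' @param threshold Minimum confidence in \[0, 1\].
#' @return The retained records, input order preserved.
#' @export
filter_by_confidence <- function(records, threshold = 0.4) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single number in [0, 1]", call. = FALSE)
  }
  records[records$confidence >= threshold, , drop = FALSE]
}

#' Read a seed-protein annotation table
#'
#' Two-column TSV (`symbol`, `subfamily`); header optional. Subfamily labels
#' are uppercased and must be one of RHO, RAS, RAB, ARF, RAN, RGK, OTHER.
#'
#' @param input Path or character lines, as in [parse_edge_table()].
#' @return Data frame with columns `symbol`, `subfamily`, `is_gtpase`.
#' @export
read_annotation_table <- function(input) {
  lines <- read_input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(symbol = character(), subfamily = character(),
                      is_gtpase = logical(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  h2 <- if (length(fields[[1]]) >= 2) toupper(trimws(fields[[1]][2])) else ""
  if (h2 == "SUBFAMILY") fields <- fields[-1]
  sym <- canonical_symbols(vapply(fields, `[`, "", 1L))
  sf <- canonical_symbols(vapply(fields, `[`, "", 2L))
  bad <- which(!sf %in% SUBFAMILIES)
  if (length(bad)) {
    stop(sprintf("unknown subfamily label '%s' (expected one of %s)",
                 sf[bad[1]], paste(SUBFAMILIES, collapse = ", ")),
         call. = FALSE)
  }
  data.frame(symbol = sym, subfamily = sf, is_gtpase = sf != "OTHER",
             stringsAsFactors = FALSE)
}

#' Build an undirected simple interaction network from records
#'
#' Self-loops are dropped, and reciprocal or repeated pairs are collapsed to
#' a single undirected edge (the first record for a pair supplies the
#' confidence and evidence attributes). Symbols present in the annotation
#' table but absent from the retained edges are kept as zero-degree nodes,
#' so curated GTPases without interaction partners remain network members.
#' Unannotated symbols become `OTHER` (non-GTPase) nodes.
#'
#' @param records Interaction records.
#' @param annotations Optional annotation data frame
#'   (see [read_annotation_table()]).
#' @return An igraph object with vertex attributes `subfamily` and
#'   `is_gtpase` and edge attributes `confidence` and `evidence`.
#' @examples
#' recs <- parse_edge_table(c("A\tB\t0.9\texp", "B\tA\t0.9\texp", "C\tC\t0.5\texp"))
#' g <- build_network(recs)
#' igraph::ecount(g)  # 1: the reciprocal pair collapses, the self-loop drops
#' @export
build_network <- function(records, annotations = NULL) {
  a <- canonical_symbols(records$protein_a)
  b <- canonical_symbols(records$protein_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  conf <- records$confidence[keep]
  ev <- (records$evidence %||% rep("", length(keep)))[keep]
  cp <- canonical_pairs(a, b)
  first <- !duplicated(cp$key)
  sf <- NULL
  extra <- NULL
  if (!is.null(annotations) && nrow(annotations) > 0) {
    sf <- stats::setNames(annotations$subfamily,
                          canonical_symbols(annotations$symbol))
    extra <- names(sf)
  }
  graph_from_pairs(a[first], b[first], vertices = extra,
                   confidence = conf[first], evidence = ev[first],
                   subfamily = sf)
}

#' Union of interaction networks
#'
#' Node and edge sets are unioned; a duplicated edge keeps the highest
#' confidence seen for it. Subfamily labels are merged, with the neutral
#' `OTHER` label absorbed by any specific subfamily; two conflicting
#' specific labels for the same symbol raise an error.
#'
#' @param networks A list of interaction networks (igraph objects).
#' @return The merged interaction network.
#' @export
net_union <- function(networks) {
  if (!is.list(networks) || length(networks) < 1) {
    stop("`networks` must be a non-empty list", call. = FALSE)
  }
  lapply(networks, assert_network)
  sym <- character(); sf <- character()
  a <- character(); b <- character(); conf <- numeric(); ev <- character()
  for (g in networks) {
    sym <- c(sym, node_names(g))
    sfg <- igraph::vertex_attr(g, "subfamily") %||%
      rep("OTHER", igraph::vcount(g))
    sf <- c(sf, sfg)
    el <- igraph::as_edgelist(g)
    a <- c(a, el[, 1]); b <- c(b, el[, 2])
    conf <- c(conf, igraph::edge_attr(g, "confidence") %||%
                rep(1.0, nrow(el)))
    ev <- c(ev, igraph::edge_attr(g, "evidence") %||% rep("", nrow(el)))
  }
  lab <- tapply(sf, sym, function(x) {
    u <- setdiff(unique(x), "OTHER")
    if (length(u) > 1) {
      stop("conflicting subfamily labels in union: ",
           paste(u, collapse = " vs "), call. = FALSE)
    }
    if (length(u) == 1) u else "OTHER"
  })
  lab <- stats::setNames(as.character(lab), names(lab))
  cp <- canonical_pairs(a, b)
  ord <- order(cp$key, -conf)  # keep highest confidence per edge
  first <- !duplicated(cp$key[ord])
  idx <- ord[first]
  graph_from_pairs(a[idx], b[idx], vertices = names(lab),
                   confidence = conf[idx], evidence = ev[idx],
                   subfamily = lab)
}

#' Remove a blacklist of edges from a network
#'
#' Unordered pairs listed in the blacklist are removed when present; pairs
#' absent from the graph are ignored. Used to drop interactions whose
#' supporting citations failed manual re-curation.
#'
#' @param network An interaction network.
#' @param blacklist Two-column matrix or data frame of symbol pairs.
#' @return The network without the listed edges.
#' @export
exclude_edges <- function(network, blacklist) {
  assert_network(network)
  if (is.null(blacklist) || NROW(blacklist) == 0) return(network)
  bl <- as.matrix(blacklist)
  pa <- canonical_symbols(bl[, 1])
  pb <- canonical_symbols(bl[, 2])
  el <- igraph::as_edgelist(network)
  want <- canonical_pairs(pa, pb)$key
  have <- canonical_pairs(el[, 1], el[, 2])$key
  igraph::delete_edges(network, which(have %in% want))
}

#' Summarize interaction confidence scores
#'
#' Population mean and standard deviation, with counts in half-open bins
#' `[x, x + width)`; the final bin is closed at 1.0 so a perfect score is
#' counted.
#'
#' @param records Interaction records (must be non-empty).
#' @param bin_width Bin width on the confidence axis.
#' @return An object of class `confidence_summary`: list with `n`, `mean`,
#'   `sd` (population), and named `bin_counts`.
#' @export
confidence_summary <- function(records, bin_width = 0.1) {
  x <- records$confidence
  if (length(x) == 0) stop("no records to summarize", call. = FALSE)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  labels <- sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1],
                    c(rep(")", length(breaks) - 2), "]"))
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  names(counts) <- labels
  structure(list(n = length(x), mean = mean(x),
                 sd = sqrt(mean((x - mean(x))^2)), bin_counts = counts),
            class = "confidence_summary")
}

#' @export
print.confidence_summary <- function(x, ...) {
  cat(sprintf("Confidence scores: n = %d, mean = %.3f, sd = %.3f\n",
              x$n, x$mean, x$sd))
  nz <- x$bin_counts[x$bin_counts > 0]
  for (i in seq_along(nz)) cat(sprintf("  %-12s %d\n", names(nz)[i], nz[i]))
  invisible(x)
}

#' Curation outcome report
#'
#' Summarizes a manual literature re-curation step: of `n_considered`
#' database-reported interactions, `n_unsupported` could not be confirmed.
#' The confirmed percentage is kept at full precision internally and
#' rendered to one decimal.
#'
#' @param n_considered Number of interactions inspected (> 0).
#' @param n_unsupported Number that could not be confirmed.
#' @return An object of class `curation_stats` with `n_considered`,
#'   `n_unsupported`, `pct_confirmed` (unrounded) and
#'   `pct_confirmed_rendered`.
#' @examples
#' curation_report(429, 7)$pct_confirmed_rendered  # 98.4
#' @export
curation_report <- function(n_considered, n_unsupported) {
  if (length(n_considered) != 1 || n_considered <= 0) {
    stop("`n_considered` must be a single positive count", call. = FALSE)
  }
  if (n_unsupported < 0 || n_unsupported > n_considered) {
    stop("`n_unsupported` must lie in [0, n_considered]", call. = FALSE)
  }
  pct <- 100 * (n_considered - n_unsupported) / n_considered
  structure(list(n_considered = n_considered, n_unsupported = n_unsupported,
                 pct_confirmed = pct,
                 pct_confirmed_rendered = round_half_up(pct, 1)),
            class = "curation_stats")
}

#' @export
print.curation_stats <- function(x, ...) {
  cat(sprintf("Curation: %d of %d confirmed (%.1f%%)\n",
              x$n_considered - x$n_unsupported, x$n_considered,
              x$pct_confirmed_rendered))
  invisible(x)
}
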