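# Internal helpers shared across modules.

# Canonical unordered edge key: lexicographically smaller symbol first.
canonical_pairs <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  list(lo = lo, hi = hi, key = paste(lo, hi, sep = "\r"))
}

# Round half away from zero, matching the rendering used in printed tables
# (base round() ties to even, which would turn 1.25 into 1.2).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_network <- function(network) {
  if (!igraph::is_igraph(network)) {
    stop("`network` must be an igraph object built by build_network() or a generator",
         call. = FALSE)
  }
  invisible(network)
}

# Clean gene symbols: strip surrounding whitespace, uppercase.
canonical_symbols <- function(x) toupper(trimws(x))

node_names <- function(network) {
  nm <- igraph::vertex_attr(network, "name")
  if (is.null(nm)) as.character(seq_len(igraph::vcount(network))) else nm
}

# Deterministic igraph constructor: vertices sorted, edges canonicalised.
graph_from_pairs <- function(a, b, vertices = NULL, confidence = NULL,
                             evidence = NULL, subfamily = NULL) {
  cp <- canonical_pairs(a, b)
  ord <- order(cp$lo, cp$hi)
  el <- cbind(cp$lo[ord], cp$hi[ord])
  verts <- sort(unique(c(cp$lo, cp$hi, vertices)))
  df_v <- data.frame(name = verts, stringsAsFactors = FALSE)
  if (!is.null(subfamily)) {
    sf <- subfamily[verts]
    sf[is.na(sf)] <- "OTHER"
    df_v$subfamily <- unname(sf)
    df_v$is_gtpase <- df_v$subfamily != "OTHER"
  } else {
    df_v$subfamily <- "OTHER"
    df_v$is_gtpase <- FALSE
  }
  df_e <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  if (!is.null(confidence)) df_e$confidence <- confidence[ord]
  if (!is.null(evidence)) df_e$evidence <- evidence[ord]
  igraph::graph_from_data_frame(df_e, directed = FALSE, vertices = df_v)
}
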