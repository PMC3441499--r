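#' Read a two-column term/gene annotation table
#'
#' TSV with columns `term`, `gene` (header optional, detected by the
#' literal first cell "term").
#'
#' @param input Path or character lines.
#' @return Named list: term -> character vector of gene symbols.
#' @export
read_annotation_pairs <- function(input) {
  lines <- read_input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && tolower(trimws(fields[[1]][1])) == "term") {
    fields <- fields[-1]
  }
  term <- vapply(fields, `[`, "", 1L)
  gene <- canonical_symbols(vapply(fields, `[`, "", 2L))
  lapply(split(gene, term), function(x) sort(unique(x)))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> genes...`.
#'
#' @param input Path or character lines.
#' @return Named list: set name -> character vector of gene symbols.
#' @export
read_gmt <- function(input) {
  lines <- read_input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3) {
      stop("malformed GMT line (need name, description, >= 1 gene)",
           call. = FALSE)
    }
    out[[tok[1]]] <- sort(unique(canonical_symbols(tok[3:length(tok)])))
  }
  out
}

#' Over-representation test of a gene list against annotation terms
#'
#' One-sided upper-tail hypergeometric test per term (Fisher's exact test
#' for enrichment): with background size N, term size K, query size n and
#' overlap k, `p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n)`. The EASE
#' variant removes one gene from the overlap (k replaced by max(k - 1, 0))
#' before taking the tail, giving a conservative score that penalizes
#' single-gene overlaps. Query symbols outside the background are dropped
#' with a message. No multiple-testing correction is applied here;
#' [filter_significant()] can apply Benjamini-Hochberg on request.
#'
#' @param query Character vector of gene symbols.
#' @param annotations Named list: term -> gene symbols, or an annotation
#'   table read by [read_annotation_pairs()] / [read_gmt()].
#' @param background Optional character vector; defaults to the union of
#'   all annotated genes.
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p_fisher`,
#'   `p_ease`, one row per term.
#' @examples
#' anno <- list(path = LETTERS[1:5])
#' fisher_enrichment(LETTERS[2:5], anno, background = LETTERS[1:10])
#' @export
fisher_enrichment <- function(query, annotations, background = NULL) {
  if (length(annotations) == 0) stop("no annotation terms", call. = FALSE)
  annotations <- lapply(annotations, canonical_symbols)
  background <- canonical_symbols(background %||%
                                    unique(unlist(annotations)))
  background <- unique(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  query <- unique(canonical_symbols(query))
  dropped <- setdiff(query, background)
  if (length(dropped)) {
    message(length(dropped), " query symbol(s) outside the background dropped")
  }
  query <- intersect(query, background)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(annotations), function(tm) {
    genes <- intersect(annotations[[tm]], background)
    K <- length(genes)
    k <- length(intersect(query, genes))
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p_fisher = hyper_upper_tail(k, K, N, n),
               p_ease = hyper_upper_tail(max(k - 1, 0), K, N, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# P(X >= k) for X ~ Hypergeometric(N, K, n).
hyper_upper_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Filter enrichment results at a significance level
#'
#' Retains terms with the selected p value at or below `alpha` (inclusive),
#' sorted ascending. Optionally applies Benjamini-Hochberg adjustment to
#' the selected statistic before filtering.
#'
#' @param results Data frame from [fisher_enrichment()].
#' @param alpha Significance level in (0, 1\].
#' @param stat `"fisher"` or `"ease"`.
#' @param adjust Apply Benjamini-Hochberg before thresholding.
#' @return The retained rows, sorted by the selected p value.
#' @export
filter_significant <- function(results, alpha = 0.05,
                               stat = c("fisher", "ease"), adjust = FALSE) {
  stat <- match.arg(stat)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (nrow(results) == 0) return(results)
  p <- results[[paste0("p_", stat)]]
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  out <- results[p <= alpha, , drop = FALSE]
  out[order(p[p <= alpha]), , drop = FALSE]
}
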