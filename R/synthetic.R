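#' Partial-duplication network growth
#'
#' Grows a graph by gene-duplication dynamics: starting from a small
#' complete seed graph, a uniformly chosen existing node is copied and the
#' copy inherits each of the template's edges independently with
#' probability `p_retain`. Copies that inherit no edge are redrawn by
#' default, so the target size is reached without spraying isolates; set
#' `keep_isolates = TRUE` to keep them instead (emulating curated proteins
#' with no recovered partners). Partial duplication (p_retain < 1)
#' produces heavy-tailed degree distributions with fitted exponents in the
#' 1-2 range typical of protein interaction networks, in contrast to
#' preferential attachment.
#'
#' @param n_target Final node count.
#' @param p_retain Probability each template edge is inherited, in (0, 1\].
#' @param seed_graph_size Size of the initial complete graph (>= 3).
#' @param rng_seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param keep_isolates Keep copies that inherit no edges.
#' @return An interaction network (igraph, nodes named `D0001`, ...).
#' @export
generate_partial_duplication <- function(n_target, p_retain = 0.45,
                                         seed_graph_size = 3, rng_seed = 1L,
                                         keep_isolates = FALSE) {
  if (p_retain <= 0 || p_retain > 1) {
    stop("`p_retain` must lie in (0, 1]", call. = FALSE)
  }
  if (seed_graph_size < 3) stop("`seed_graph_size` must be >= 3", call. = FALSE)
  if (n_target < seed_graph_size) {
    stop("`n_target` must be >= seed_graph_size", call. = FALSE)
  }
  withr::with_seed(as.integer(rng_seed), {
    s <- seed_graph_size
    adj <- lapply(seq_len(s), function(i) setdiff(seq_len(s), i))
    while (length(adj) < n_target) {
      src <- sample.int(length(adj), 1L)
      nb <- adj[[src]]
      keep <- nb[stats::runif(length(nb)) < p_retain]
      if (length(keep) == 0L && !keep_isolates) next
      new <- length(adj) + 1L
      adj[[new]] <- keep
      for (u in keep) adj[[u]] <- c(adj[[u]], new)
    }
  })
  adj_to_graph(adj, prefix = "D")
}

adj_to_graph <- function(adj, prefix) {
  nm <- sprintf("%s%04d", prefix, seq_along(adj))
  rows <- lapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  })
  el <- do.call(rbind, rows)
  if (is.null(el)) {
    return(graph_from_pairs(character(), character(), vertices = nm))
  }
  graph_from_pairs(nm[el[, 1]], nm[el[, 2]], vertices = nm)
}

#' Preferential-attachment ("rich get richer") network growth
#'
#' Starts from a complete graph on `m + 1` nodes; each new node attaches
#' to `m` distinct existing nodes chosen with probability proportional to
#' their current degree. The resulting graph is simple, with
#' `m * (n - m - 1) + choose(m + 1, 2)` edges, and its fitted degree
#' exponent is markedly steeper than the partial-duplication regime.
#'
#' @param n Final node count (> m).
#' @param m Edges added per new node (>= 1).
#' @param rng_seed Integer seed.
#' @return An interaction network (igraph, nodes named `B0001`, ...).
#' @export
generate_preferential_attachment <- function(n, m, rng_seed = 1L) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (n <= m) stop("`n` must exceed `m`", call. = FALSE)
  withr::with_seed(as.integer(rng_seed), {
    s <- m + 1L
    adj <- lapply(seq_len(s), function(i) setdiff(seq_len(s), i))
    # multiset of edge endpoints: sampling uniformly from it is sampling
    # nodes proportional to degree
    stubs <- unlist(lapply(seq_len(s), function(i) rep(i, m)))
    for (new in seq.int(s + 1L, length.out = n - s)) {
      targets <- integer()
      while (length(targets) < m) {
        cand <- stubs[sample.int(length(stubs), 1L)]
        if (!cand %in% targets) targets <- c(targets, cand)
      }
      adj[[new]] <- targets
      for (u in targets) adj[[u]] <- c(adj[[u]], new)
      stubs <- c(stubs, targets, rep(new, m))
    }
  })
  adj_to_graph(adj, prefix = "B")
}

#' Erdos-Renyi random graph G(n, p)
#'
#' Every unordered node pair is an edge independently with probability
#' `p_edge`; degrees are approximately Poisson, the contrast case to the
#' heavy-tailed generators.
#'
#' @param n Node count.
#' @param p_edge Edge probability in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return An interaction network (igraph, nodes named `N0001`, ...).
#' @export
generate_er <- function(n, p_edge, rng_seed = 1L) {
  if (p_edge < 0 || p_edge > 1) stop("`p_edge` must lie in [0, 1]", call. = FALSE)
  g <- withr::with_seed(as.integer(rng_seed),
                        igraph::sample_gnp(n, p_edge, directed = FALSE))
  nm <- sprintf("N%04d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  graph_from_pairs(nm[el[, 1]], nm[el[, 2]], vertices = nm)
}

#' Specification for a synthetic STRING-style fixture
#'
#' Defaults emulate the curated GTPase network's study conditions: 141
#' searched GTPase seeds across the six subfamilies (of which 98 have at
#' least one interaction), 778 total proteins and 1943 edges, hub degrees
#' 134/110/96/77 with a second tier at 53/45/38/35, confidence scores from
#' a normal(0.66, 0.146) truncated to \[0.4, 1\], and the published
#' cross-subfamily shared-protein combination counts (84 shared proteins,
#' one of them in four subfamily networks).
#'
#' @param subfamily_sizes Named integer vector: searched seeds per
#'   subfamily.
#' @param connected_per_subfamily Named integer vector: seeds that must
#'   appear in at least one interaction.
#' @param n_total Total protein count (seeds + partner proteins).
#' @param n_edges Total edge count.
#' @param hub_table Data frame `symbol`, `subfamily`, `degree`: GTPase hubs
#'   with exact planted degrees.
#' @param planted_overlaps Named integer vector: label combination (sorted,
#'   joined with `+`) -> number of partner proteins planted in exactly
#'   those subfamily networks.
#' @param confidence_mean,confidence_sd,confidence_floor Truncated-normal
#'   confidence score model.
#' @param rng_seed Integer seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(
    subfamily_sizes = c(RHO = 22, RAS = 29, RAB = 59, ARF = 26, RAN = 1,
                        RGK = 4),
    connected_per_subfamily = c(RHO = 20, RAS = 19, RAB = 42, ARF = 13,
                                RAN = 1, RGK = 3),
    n_total = 778,
    n_edges = 1943,
    hub_table = data.frame(
      symbol = c("RAC1", "CDC42", "RHOA", "HRAS", "RAN", "RAP1A", "ARF1",
                 "RAB5A"),
      subfamily = c("RHO", "RHO", "RHO", "RAS", "RAN", "RAS", "ARF", "RAB"),
      degree = c(134, 110, 96, 77, 53, 45, 38, 35),
      stringsAsFactors = FALSE),
    planted_overlaps = c(
      "ARF+RAB+RAS+RHO" = 1,
      "ARF+RAB+RHO" = 1, "RAB+RAS+RHO" = 2, "ARF+RAS+RHO" = 4,
      "RAS+RHO" = 36, "RAB+RHO" = 9, "RAB+RAS" = 9, "ARF+RAB" = 8,
      "ARF+RHO" = 6, "ARF+RAS" = 5, "RAN+RHO" = 2, "ARF+RAN" = 1),
    confidence_mean = 0.66, confidence_sd = 0.146, confidence_floor = 0.4,
    rng_seed = 1L) {
  if (any(connected_per_subfamily > subfamily_sizes[names(connected_per_subfamily)])) {
    stop("connected seeds cannot exceed searched seeds", call. = FALSE)
  }
  n_partners <- n_total - sum(subfamily_sizes)
  if (n_partners <= sum(planted_overlaps)) {
    stop("infeasible spec: not enough partner proteins for the planted overlaps",
         call. = FALSE)
  }
  combo_labels <- unique(unlist(strsplit(names(planted_overlaps), "+",
                                         fixed = TRUE)))
  if (!all(combo_labels %in% names(subfamily_sizes))) {
    stop("planted overlap labels must be subfamily labels", call. = FALSE)
  }
  structure(list(subfamily_sizes = subfamily_sizes,
                 connected_per_subfamily = connected_per_subfamily,
                 n_total = n_total, n_edges = n_edges, hub_table = hub_table,
                 planted_overlaps = planted_overlaps,
                 confidence_mean = confidence_mean,
                 confidence_sd = confidence_sd,
                 confidence_floor = confidence_floor,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

# Normal(mean, sd) truncated to [floor, 1] by rejection sampling.
rtrunc_confidence <- function(n, mean, sd, floor_) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 16L, mean, sd)
    out <- c(out, draw[draw >= floor_ & draw <= 1])
  }
  out[seq_len(n)]
}

#' Generate a synthetic STRING-style edge table and annotation table
#'
#' Builds a seeded, fully reproducible stand-in for the curated GTPase
#' interaction export: GTPase seeds with hub-skewed degrees (the hub
#' degrees in `spec$hub_table` are planted exactly), partner proteins
#' planted into the requested subfamily-overlap combinations exactly, a
#' few dense partner modules for complex detection to find, a preferential
#' partner-partner tail filling the edge budget exactly, and truncated
#' normal confidence scores. Seeds without interactions appear only in the
#' annotation table, so building the network keeps them as isolated nodes.
#'
#' @param spec A [fixture_spec()] object.
#' @return List with `edges` (data frame `protein_a`, `protein_b`,
#'   `confidence`, `evidence`), `annotations` (data frame `symbol`,
#'   `subfamily`, `is_gtpase`), `seed_table` (named list label -> searched
#'   symbols), and `spec`.
#' @export
generate_string_fixture <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop("`spec` must be a fixture_spec",
                                            call. = FALSE)
  labels <- names(spec$subfamily_sizes)
  hubs <- spec$hub_table
  # seed symbols per subfamily: named hubs first, then synthetic fill
  seed_table <- lapply(labels, function(lab) {
    named <- hubs$symbol[hubs$subfamily == lab]
    need <- spec$subfamily_sizes[[lab]] - length(named)
    c(named, sprintf("%s%02d", lab, seq_len(max(need, 0))))
  })
  names(seed_table) <- labels
  connected <- lapply(labels, function(lab) {
    seed_table[[lab]][seq_len(spec$connected_per_subfamily[[lab]])]
  })
  names(connected) <- labels
  connected_all <- unlist(connected, use.names = FALSE)
  non_hub_connected <- setdiff(connected_all, hubs$symbol)
  n_partners <- spec$n_total - sum(spec$subfamily_sizes)
  partners <- sprintf("PRT%04d", seq_len(n_partners))

  seen <- new.env(hash = TRUE, parent = emptyenv())
  ea <- character(spec$n_edges); eb <- character(spec$n_edges)
  n_e <- 0L
  add_edge <- function(u, v) {
    if (u == v) return(FALSE)
    key <- if (u < v) paste(u, v, sep = "\r") else paste(v, u, sep = "\r")
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- TRUE
    n_e <<- n_e + 1L
    ea[n_e] <<- u; eb[n_e] <<- v
    TRUE
  }

  # Non-overlap partners may only ever receive seed-incident edges from a
  # single subfamily; otherwise hub stars would create unplanned shared
  # proteins and the overlap combinations would no longer be exact.
  fam_of <- new.env(hash = TRUE, parent = emptyenv())
  fam_ok <- function(prt, lab) {
    f <- fam_of[[prt]]
    is.null(f) || identical(f, lab)
  }

  withr::with_seed(spec$rng_seed, {
    # 1. planted cross-subfamily shared proteins
    overlap_partners <- character(0)
    p_i <- 0L
    for (combo in names(spec$planted_overlaps)) {
      labs <- strsplit(combo, "+", fixed = TRUE)[[1]]
      for (rep_i in seq_len(spec$planted_overlaps[[combo]])) {
        p_i <- p_i + 1L
        prt <- partners[p_i]
        overlap_partners <- c(overlap_partners, prt)
        for (lab in labs) {
          pool <- connected[[lab]]
          add_edge(prt, pool[sample.int(length(pool), 1L)])
        }
      }
    }
    # 2. dense partner modules (complex-detection targets), each anchored
    #    to a hub by two edges
    module_sizes <- c(12L, 8L, 6L)
    module_dens <- c(0.65, 0.7, 0.8)
    for (mi in seq_along(module_sizes)) {
      mem <- partners[p_i + seq_len(module_sizes[mi])]
      p_i <- p_i + module_sizes[mi]
      prs <- utils::combn(mem, 2)
      take <- stats::runif(ncol(prs)) < module_dens[mi]
      for (j in which(take)) add_edge(prs[1, j], prs[2, j])
      anchor_i <- sample.int(nrow(hubs), 1L)
      for (u in mem[seq_len(2L)]) {
        add_edge(u, hubs$symbol[anchor_i])
        fam_of[[u]] <- hubs$subfamily[anchor_i]
      }
    }
    # 3. hub stars: top up each named hub to its exact planted degree,
    #    avoiding overlap partners (their combinations must stay exact)
    #    and partners already claimed by another subfamily
    star_pool <- setdiff(partners, overlap_partners)
    cur_deg <- function(sym) sum(ea[seq_len(n_e)] == sym) +
      sum(eb[seq_len(n_e)] == sym)
    for (h in seq_len(nrow(hubs))) {
      sym <- hubs$symbol[h]
      lab <- hubs$subfamily[h]
      need <- hubs$degree[h] - cur_deg(sym)
      taken <- c(ea[seq_len(n_e)][eb[seq_len(n_e)] == sym],
                 eb[seq_len(n_e)][ea[seq_len(n_e)] == sym])
      avail <- setdiff(star_pool, taken)
      avail <- avail[vapply(avail, fam_ok, TRUE, lab = lab)]
      if (need > length(avail)) {
        stop("infeasible spec: hub degree exceeds available partners",
             call. = FALSE)
      }
      if (need > 0) {
        for (u in sample(avail, need)) {
          add_edge(sym, u)
          fam_of[[u]] <- lab
        }
      }
    }
    # 4. every connected seed participates in >= 1 interaction
    deg_tab <- table(c(ea[seq_len(n_e)], eb[seq_len(n_e)]))
    for (lab in labels) {
      for (sym in connected[[lab]]) {
        if (is.na(deg_tab[sym])) {
          pool <- setdiff(partners, overlap_partners)
          pool <- pool[vapply(pool, fam_ok, TRUE, lab = lab)]
          prt <- sample(pool, 1L)
          add_edge(sym, prt)
          fam_of[[prt]] <- lab
        }
      }
    }
    # 5. every partner appears: untouched partners attach to a non-hub
    #    connected seed, heavier-ranked seeds favoured (heavy-tailed seed
    #    degrees without disturbing the planted hub degrees)
    deg_tab <- table(c(ea[seq_len(n_e)], eb[seq_len(n_e)]))
    loose <- partners[!partners %in% names(deg_tab)]
    wt <- (seq_along(non_hub_connected))^-0.8
    seed_fam <- rep(labels, vapply(labels, function(l)
      length(setdiff(connected[[l]], hubs$symbol)), 1L))
    for (prt in loose) {
      j <- sample.int(length(non_hub_connected), 1L, prob = wt)
      add_edge(prt, non_hub_connected[j])
      fam_of[[prt]] <- seed_fam[j]
    }
    if (n_e > spec$n_edges) {
      stop("infeasible spec: planted structure already exceeds `n_edges`",
           call. = FALSE)
    }
    # 6. fill the edge budget with preferential partner-partner edges
    guard <- 0L
    while (n_e < spec$n_edges && guard < 200L * spec$n_edges) {
      guard <- guard + 1L
      deg_tab <- table(factor(c(ea[seq_len(n_e)], eb[seq_len(n_e)]),
                              levels = partners))
      w <- as.numeric(deg_tab) + 0.25
      budget <- spec$n_edges - n_e
      cand_a <- partners[sample.int(n_partners, 2L * budget, replace = TRUE,
                                    prob = w)]
      cand_b <- partners[sample.int(n_partners, 2L * budget, replace = TRUE,
                                    prob = w)]
      for (j in seq_along(cand_a)) {
        if (n_e >= spec$n_edges) break
        add_edge(cand_a[j], cand_b[j])
      }
    }
    if (n_e < spec$n_edges) {
      stop("could not reach the requested edge count", call. = FALSE)
    }
    conf <- round(rtrunc_confidence(n_e, spec$confidence_mean,
                                    spec$confidence_sd,
                                    spec$confidence_floor), 3)
  })
  edges <- data.frame(protein_a = ea, protein_b = eb, confidence = conf,
                      evidence = "synthetic", stringsAsFactors = FALSE)
  annotations <- data.frame(
    symbol = unlist(seed_table, use.names = FALSE),
    subfamily = rep(labels, lengths(seed_table)),
    stringsAsFactors = FALSE)
  annotations$is_gtpase <- TRUE
  list(edges = edges, annotations = annotations, seed_table = seed_table,
       spec = spec)
}
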