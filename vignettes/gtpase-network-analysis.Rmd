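---
title: "Topology, modules and null models for the small GTPase interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology, modules and null models for the small GTPase interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtpnet)
```

## The problem

Small GTP-binding proteins of the Ras superfamily (the Rho, Ras, Rab, Arf,
Ran and RGK subfamilies) act as molecular switches in signalling, vesicle
traffic, cytoskeleton dynamics and nuclear transport. Their pathways are
known to cross-talk through shared effectors, regulators (GEFs, GAPs, GDIs)
and direct GTPase–GTPase contacts. A systems-level way to study this
interplay is to assemble all experimentally supported protein–protein
interactions involving the curated GTPases into one undirected graph and to
ask structural questions of it: is the degree distribution heavy-tailed,
which proteins are hubs, which are bottlenecks, which dense modules look
like complexes, and is the observed clustering more than a degree artefact?

`gtpnet` implements that complete analysis as a set of composable,
deterministic operations, together with a synthetic-data module that
emulates the statistical structure of the curated dataset so the whole
pipeline can be developed and tested offline.

## Data model and ingestion

An interaction record is a pair of gene symbols with a confidence score in
[0, 1] (STRING combined-score scale) and a free-text evidence tag. Records
arrive as tab-separated edge tables or SIF files; symbols are uppercased
and stripped, with no alias resolution (identifier mapping is an
external-database concern). Records at or above the confidence threshold —
default 0.4, the STRING "medium confidence" level, and *inclusive* so a
score of exactly 0.4 is kept — are merged into an undirected simple graph:
self-loops are dropped, reciprocal detections collapse to one edge, and
edges are stored orientation-free with lexicographic canonical ordering so
every export is byte-stable. Curated GTPases that appear in the annotation
table but in no retained record are kept as zero-degree nodes: the curated
seed list, not the edge table, defines network membership for GTPases.
Because the searched seed-list size is itself a curation decision (published
counts of the searched list disagree, 139 vs 141), it is a parameter of the
annotation table, never a constant in code.

## Topology

The degree distribution counts N(k), the number of nodes with k
neighbours. The scale-free hypothesis is assessed with the field's classic
log–log regression: ordinary least squares of log10 N(k) on log10 k over
degrees k ≥ 1 with N(k) > 0, no binning. The degree exponent γ is the
negated slope, so the fitted law is N(k) = c·k^(−γ). Zero-count degrees
are skipped (their logarithm is undefined) and k = 0 nodes appear in the
distribution but not in the fit. This convention — raw counts, unbinned,
least squares — is deliberately the one used by the graph-analysis tools
this pipeline mirrors; it is *not* a maximum-likelihood tail estimator,
and the vignette section on growth models below discusses the finite-size
bias this implies.

The local clustering coefficient of a node with degree d ≥ 2 is the number
of edges among its neighbours divided by d(d−1)/2; nodes with fewer than
two neighbours are assigned 0, and the global coefficient is the plain
arithmetic mean over *all* nodes. Shortest-path statistics are computed by
breadth-first search over all unordered reachable pairs; disconnected
pairs are excluded rather than counted as infinite, which keeps the mean
finite on a graph with satellite components and isolated GTPases.

Hubs are identified by a gap rule rather than a fixed fraction: within the
top decile of the descending degree sequence, the largest consecutive drop
separates the hubs from the rest, and the largest drop after that bounds a
second tier. A verbal "top ~20%" rule cannot produce a four-protein hub
set out of hundreds of nodes; the gap rule recovers exactly the two-tier
structure that a bimodal degree sequence displays, with no tuned
parameter. Ties in gap size resolve toward the deeper cut (the more
inclusive hub set). A `top_fraction` method is also provided; it keeps the
top `floor(param·n)` ranks with ties at the threshold expanded, so every
hub degree is at least every non-hub degree. Hub influence is summarised
as a degree share: the tier's summed degrees over the edge count, e.g.
degrees 134 + 110 + 96 + 77 against 1943 edges give 21.5%.

## Bottlenecks

Bottlenecks are ranked by unnormalized shortest-path betweenness over
unordered pairs, with fractional credit: a pair (s, t) distributes one
unit across its shortest paths, so an interior node receives
σ_st(v)/σ_st. This is the convention of the standard network-analysis
plugins, and normalization is irrelevant to a ranking. Because the exact
scoring variant behind the original tool is not documented, a strict-count
mode (a pair credits a node 1 if *any* shortest path passes through it) is
available for sensitivity analysis; both modes are verified in the test
suite against an exhaustive all-shortest-paths enumeration on every test
graph up to 12 nodes. The top-k report expands ties at the cutoff and
intersects with the hub set to flag hub-bottlenecks, and a companion
operation reports pairwise path lengths within the top set, flagging pairs
more than three steps apart.

## Complex detection

Module discovery follows the MCODE scheme: score each vertex by the
density of its neighbourhood core, then grow clusters greedily from
high-scoring seeds.

* **Vertex weighting.** A vertex with degree below the degree cutoff
  (default 2) weighs 0. Otherwise the highest k-core of its *closed*
  neighbourhood is found and the weight is k × density of that core. The
  density convention throughout is loop-inclusive, DC = E/V².
* **Growth.** Starting from the highest-weight unvisited vertex (ties
  broken lexicographically for deterministic output), breadth-first
  expansion admits neighbours whose weight is at least (1 − node score
  cutoff) times the seed's weight — with the default cutoff 0.2, at least
  80% of the seed. Visited vertices are never reused, so clusters are
  node-disjoint. Growth depth is bounded by `max_depth` (default 100,
  effectively unbounded on graphs of this diameter).
* **Post-processing.** Haircut (default on) iteratively removes members
  with fewer than two within-cluster edges; clusters whose induced
  subgraph lacks a k-core of at least `k_core` (default 3) are discarded;
  the optional fluff step is off by default. The order is grow → haircut →
  k-core filter → score.
* **Score.** DC × V = (E/V²)·V = E/V, internal edges per member, rendered
  to one decimal. The loop-inclusive density is not an aesthetic choice:
  it is the only convention under which every published score/nodes/edges
  triple of the reference analysis is reproduced exactly (the loop-free
  alternative E/(V(V−1)/2) contradicts them), and the test suite asserts
  all twelve triples.

One behaviour worth knowing: when two equally dense regions are joined by
an edge whose endpoints score as well as the region interiors (two equal
cliques bridged by a single edge is the canonical case), seeded growth
legitimately crosses the bridge and returns one cluster. Splitting such a
dumbbell requires a weighting that penalizes the bridge endpoints, which
the core-density definition above does not; the tests freeze the derived
single-cluster outcome.

A single global weighting pass is used; per-cluster re-weighting of
unvisited vertices is not (whether the original tool re-weighted is
undocumented, and a single pass keeps results order-independent).

## Degree-preserving null model

The null model rewires the observed graph while conserving every node's
degree: repeatedly select two edges (u,v) and (s,t) and replace them with
(u,t) and (s,v), requiring that all four endpoints be pairwise distinct
and that neither replacement edge already exist. Pairwise distinctness is
the safe reading of the constraint chain u ≠ v ≠ s ≠ t: allowing u = t
would permit a replacement self-loop. The second edge's orientation is
randomized per proposal so the swap chain is reversible over the whole
configuration space. The target is 10 successful swaps per edge (a
standard mixing heuristic — the source analysis does not state a count),
with an attempt budget of 100 proposals per targeted success; degenerate
graphs that admit no valid swap (a triangle, a complete graph) come back
unchanged with a warning. Degree sequence and edge count are exactly
invariant for every seed, which the tests assert across 50 seeds.

A null ensemble runs 100 independent rewires (replicate r is seeded
`seed + r`), computes the global clustering of each, and summarises with
the mean and the sample (n−1) standard deviation — at n = 100 the
distinction from the population SD is far below reporting precision. The
one-sample Z test reports both conventions: z_sd = (obs − mean)/sd and
z_se = (obs − mean)/(sd/√n), with the two-sided p from the normal tail of
z_se. The sign convention is observed minus null, so excess clustering is
positive; analyses that subtract in the other order will print the same
magnitude with the opposite sign. A degenerate ensemble (sd = 0) yields
±Inf with p = 0 when the observed value differs from the null mean.

The randomized-graph MCODE control rewires once and reruns the complex
search with identical parameters. Note a structural fact that shapes what
this control can show: degrees are conserved, so a graph whose minimum
degree is at least 3 still contains a 3-core after any rewiring. The
control is informative precisely when the dense modules are embedded in a
sparse background — then rewiring disperses the module edges and the
k-core filter empties the result, which is the behaviour the test suite
demonstrates on a cliques-in-a-chain construction.

## Cross-talk between subfamily networks

A subfamily network is the seeds of one subfamily plus their first
neighbours, keeping only seed-incident edges — the membership rule implied
by building per-GTPase query networks and merging them. A protein present
in at least two subfamily networks is a shared (cross-talk) protein;
the report groups shared proteins by count and by exact label combination.
Seed GTPases can themselves be shared members of other subfamilies'
networks (GTPase–GTPase edges are real); a flag controls whether seeds are
counted, and both modes are reported since the convention in the reference
analysis is unstated. Coverage statistics count, per subfamily, how many
searched seeds appear in at least one record.

## Over-representation

Enrichment of a gene list against a user-supplied annotation table (term →
gene TSV, or GMT) uses the one-sided upper-tail hypergeometric probability
— Fisher's exact test for enrichment — computed with R's `phyper`, which
works in log space and is stable at genome-scale backgrounds. The EASE
variant recomputes the tail after removing one gene from the overlap
(k → max(k−1, 0)), a conservative score that sends single-gene overlaps to
p = 1. Filtering retains terms with p ≤ α (default 0.05, inclusive), with
no multiple-testing correction by default — matching the reference
filtering practice — and Benjamini–Hochberg available behind a flag for
responsible reuse. The background defaults to the union of annotated
genes and can be set to the full network node set; both choices are
legitimate and the difference is documented output, not hidden state.
No pathway or domain content ships with the package: those tables are
database snapshots, and enrichment against a 2012 snapshot is not
reproducible science.

## The synthetic data module

The curated STRING export is not redistributable, so the fixture generator
produces a stand-in with the statistical structure the analysis assumes.
Its defaults are the study conditions of the reference dataset:

* 141 searched GTPase seeds (Rho 22, Ras 29, Rab 59, Arf 26, Ran 1,
  RGK 4), of which 98 appear in at least one interaction (20/19/42/13/1/3
  per subfamily); the remaining 43 stay as isolated annotated nodes.
* 778 proteins and exactly 1943 edges.
* Planted hub degrees 134/110/96/77 (RAC1, CDC42, RHOA, HRAS) with a
  second tier 53/45/38/35 (RAN, RAP1A, ARF1, RAB5A) — exact by
  construction, so the degree-gap hub rule has a planted ground truth.
* Planted cross-subfamily shared proteins matching the reference
  combination counts exactly (84 in total: one protein in four subfamily
  networks, seven in three, seventy-six in two, 36 of them Rho+Ras). A
  per-partner subfamily ledger guarantees that no other generator stage
  creates accidental cross-subfamily membership, so overlap recovery is
  exact, not approximate.
* Confidence scores from a normal(0.66, 0.146) truncated to [0.4, 1] by
  rejection sampling. Truncation shifts the realized mean to ≈0.668 and
  shrinks the realized SD to ≈0.13; only the parameters are specified
  conditions, and the tests assert the realized mean within 0.02.
* Three dense partner modules (12/8/6 nodes at density 0.65/0.7/0.8),
  anchored to hubs, so complex detection has something real to find.
* A preferential partner–partner tail fills the edge budget, which lands
  the fitted degree exponent near 1.38 without any per-seed tuning.

What the fixture does *not* emulate: the real network's global clustering
(≈0.05 in the fixture versus 0.33 in the curated graph — the fixture
plants only three modules), its mean path length, its component
structure beyond the isolate count, and of course any actual biology of
the partner proteins. Tests that pass on the fixture therefore validate
the *machinery* (exact counting, exact planted recovery, determinism,
null-model behaviour), not the curated network's published values; those
can only be verified against the deposited graph itself.

## Growth models and the calibration of p_retain

Two growth simulators put the observed exponent in context. Partial
duplication copies a random node and retains each of its edges
independently with probability `p_retain`; copies that inherit nothing are
redrawn. Preferential attachment adds nodes with m edges to targets drawn
proportional to degree. The duplication default `p_retain = 0.45` was
calibrated once, before any downstream analysis, so that the median fitted
exponent at n = 800 sits inside the 1–2 band reported for biological
networks; the calibration sweep ships as `analysis/06_growth_models.R`
and writes the p_retain → γ table it was chosen from (0.30 → 1.63,
0.45 → 1.48, 0.60 → 1.26 at this problem size).

A caution on reading fitted exponents: the unbinned least-squares fit on
raw counts systematically underestimates steep tails, because the sparse
high-degree bins contribute many N(k) = 1 points that flatten the slope.
Pure preferential attachment, whose theoretical exponent is 3, fits at
about 1.9 at n = 2000 under this convention. The two regimes remain
cleanly separated (duplication ≈1.5, attachment ≈1.9 at these sizes, with
non-overlapping interquartile ranges), so regime comparisons should be
made with this fit convention held fixed, not against textbook asymptotic
values.

## Numerical and reporting conventions

* Rendered scores and percentages round half away from zero to one
  decimal (base R's `round` ties to even, which disagrees with how the
  reference tables are printed); full precision is kept in all returned
  objects and JSON outputs.
* All orderings (cluster ranking, bottleneck ranking, seed selection)
  break ties lexicographically so repeated runs are byte-identical.
* Thresholds are inclusive: confidence ≥ 0.4, enrichment p ≤ α, cluster
  growth weight ≥ 80% of seed.
* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; the pipeline derives per-replicate seeds as
  `seed + replicate`, so ensembles are embarrassingly reproducible.
* Degenerate inputs are contracts, not crashes: empty record sets error in
  summaries, an edgeless network errors in path statistics, a triangle
  rewires to itself with a warning, a zero-SD ensemble yields an infinite
  z with p = 0.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the reference scale (778–800
nodes, 1943 edges) with 20-replicate null ensembles for the
reproducibility contract, and the study-condition 100-replicate ensemble
in the analysis scripts; oracle comparisons run on graphs of up to 12
nodes where exhaustive path enumeration is exact; generator regime checks
use 20 seeds at n = 800 (duplication) and n = 2000 (attachment). These
sizes were chosen so each property is measured where its oracle is exact
or its distribution is tight, while a complete run stays comfortably
interactive.

## Known limitations

* The betweenness variant behind the original bottleneck ranking is
  undocumented; fractional credit is the default here and the published
  ordering is treated as a soft reference, not a contract.
* MCODE membership at the periphery is sensitive to the growth order and
  to plugin version details; cluster *scores* and geometry reproduce
  exactly, cluster membership on real data should be expected to agree
  approximately (Jaccard, not identity).
* The power-law fit is descriptive, not inferential: no likelihood
  estimation, no goodness-of-fit test against alternatives. That mirrors
  the reference convention on purpose.
* The fixture's confidence scores are independent of topology; in curated
  data, confidence correlates with degree and study bias in ways the
  generator does not model.
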