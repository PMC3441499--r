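# gtpnet

Topology, modules and null models for the small GTPase protein
interaction network.

Small GTPases of the Ras superfamily (Rho, Ras, Rab, Arf, Ran, RGK) are
molecular switches whose signalling routes cross-talk through shared
effectors, regulators and direct GTPase–GTPase contacts. `gtpnet` is an R
package, plus a numbered analysis workflow, for studying that interplay
the systems way: assemble all curated protein–protein interactions
involving the GTPase seed lists into one undirected simple graph and
characterize its architecture. It is aimed at computational biologists
who work with STRING-style curated edge tables and want every number in
the analysis to be recomputable from a seed.

## What it computes

* **Ingestion** — TSV/SIF edge tables with confidence scores; inclusive
  confidence filter (default ≥ 0.4); graph union with self-loop and
  duplicate removal; curated-seed annotation so interaction-less GTPases
  stay in the network as isolated nodes; confidence and curation-rate
  summaries.
* **Topology** — degree distribution N(k) and the scale-free exponent γ
  from the log–log least-squares fit N(k) = c·k^(−γ); local and global
  clustering coefficients (nodes with < 2 neighbours count 0); shortest
  path statistics over reachable pairs; connected components and
  isolates; hub tiers from the largest gaps in the degree sequence, with
  degree shares (e.g. degrees 134+110+96+77 of 1943 edges → 21.5%).
* **Bottlenecks** — unnormalized fractional betweenness (σ_st(v)/σ_st
  accumulation), top-k ranking with tie expansion, hub–bottleneck
  intersection, pairwise path lengths within the top set.
* **Complex detection** — MCODE-style vertex weighting (k-core number ×
  loop-inclusive density E/V² of the neighbourhood core), greedy seeded
  growth at a node-score cutoff of 0.2, haircut pruning, k-core-3 filter,
  and the score DC×V = E/V rendered to one decimal.
* **Null models** — degree-preserving edge swaps ((u,v),(s,t) →
  (u,t),(s,v) with all endpoints distinct and no duplicate edges), 100
  rewired replicates for the null clustering ensemble, one-sample Z test
  in both sd and SE conventions, and a randomized-graph MCODE control.
* **Cross-talk** — per-subfamily seed+first-neighbour networks, proteins
  shared across ≥ 2 subfamily networks grouped by exact combination,
  first-neighbour listings, seed-coverage statistics.
* **Enrichment** — Fisher (upper-tail hypergeometric) and EASE
  over-representation against user-supplied term→gene tables or GMT
  files, P ≤ 0.05 filter, optional Benjamini–Hochberg.
* **Synthetic data** — seeded generators for partial-duplication growth,
  preferential attachment, Erdős–Rényi graphs, and a STRING-style fixture
  that emulates the curated dataset's scale (778 proteins, 1943 edges),
  hub degrees, subfamily overlap counts and truncated-normal confidence
  scores, so the whole pipeline is testable offline.

## Worked example

```r
library(gtpnet)

fix <- generate_string_fixture(fixture_spec(rng_seed = 1))  # synthetic stand-in
net <- build_network(filter_by_confidence(fix$edges, 0.4), fix$annotations)

fit_power_law(degree_distribution(net))
#> Power-law fit: N(k) = 211.7 * k^-1.385 (R^2 = 0.760, 33 points)

identify_hubs(net, "degree_gap")
#> Hubs (degree_gap): RAC1, CDC42, RHOA, HRAS
#> Second tier: RAN

ens <- null_clustering_ensemble(net, n_reps = 100,
                                params = rewire_params(seed = 17))
one_sample_z(global_clustering(net)$global, ens)
#> One-sample Z: observed 0.05345 vs null 0.0643 +/- 0.0051 (n = 100)
#>   z (SE convention) = -21.29, z (SD convention) = -2.13, p = 1.56e-100
```

The fitted exponent ≈ 1.38 says the stand-in network is heavy-tailed at
the curated network's scale; the gap rule finds exactly the four planted
hubs; and the Z test shows how observed clustering is contrasted with the
degree-preserving null (this particular fixture plants only three dense
modules, so its clustering sits *below* a null that inherits the hubs'
dense neighbourhoods — on curated data the contrast runs strongly the
other way).

The full analysis, from simulated curation through growth-model
comparison, is the numbered workflow in `analysis/`:

```sh
Rscript analysis/01_simulate_network.R   # edge + annotation tables, curation rates
Rscript analysis/02_topology.R           # exponent, clustering, paths, hubs
Rscript analysis/03_modules_bottlenecks.R
Rscript analysis/04_null_models.R        # 100-replicate null ensemble + control
Rscript analysis/05_crosstalk_enrichment.R
Rscript analysis/06_growth_models.R      # duplication vs attachment, calibration
```

Each stage prints its findings and writes tables under `results/`.

## Package layout

```
R/                 implementation (io, topology, centrality, mcode,
                   null models, crosstalk, enrichment, generators, pipeline)
analysis/          numbered workflow drivers (thin scripts over R/)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests with brute-force oracles
vignettes/         methods vignette: models, conventions, design decisions
```
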