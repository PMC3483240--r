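# ppihub

Disease-gene prioritization from protein–protein interaction (PPI) network
topology, for bioinformaticians who have a disease-associated seed gene list
and want to rank candidate genes by how "hub-like" they are in the
interaction network around that list.

## What it computes

The package builds a curated, simple, undirected gene-level interaction
graph from edge-list or SIF files (isoform unification, duplicate-edge
collapse with provenance, self-loop removal) and evaluates ten standard
node-centrality indexes on it: degree, betweenness, stress, eccentricity
(reciprocal, so higher = more central), radiality, bottleneck, maximum
neighborhood component (MNC), density of the maximum neighborhood component
(DMNC), maximal clique centrality (MCC), and the Monte-Carlo edge
percolation component (EPC).

Each index *Ic_i* is min–max normalized across all *n* network nodes and
expressed as a percentage, and the composite hub score of a node is

    Score I = sum_{i=1..Nc} 100 * (Ic_i - min Ic_i) / (max Ic_i - min Ic_i)

so with *Nc* = 10 indexes the score is bounded by 100·Nc = 1000. No single
index is a reliable hub detector on its own; the sum rewards genes that are
central under many topological notions at once.

Around that core the package provides:

* **k-clique-percolation communities** (overlapping modules; nodes shared
  between communities are reported separately),
* **model-based clustering** of the normalized centrality profiles with
  in-package Gaussian-mixture EM under four covariance families and BIC
  selection (`2·logL − m·log n`, higher is better),
* **gene-set over-representation analysis** from GMT collections
  (hypergeometric and the more conservative EASE tail, Benjamini–Hochberg
  correction, set-class aggregation, annotated-universe option),
* a **differential-expression prefilter** for two-group expression
  matrices (label-permutation p-values on log2 means, symmetric ≥2-fold
  filter, BH correction) feeding the seed list,
* a **synthetic-data generator** (scale-free preferential-attachment
  backbones, planted hubs/cliques, gene-set collections with planted
  enrichment, spiked expression matrices) so the whole pipeline is testable
  without external databases, and
* `run_pipeline()`, a deterministic end-to-end orchestration with YAML
  configuration and per-stage TSV/JSON outputs.

## Worked example

```r
library(ppihub)

gen <- generate_network(n_nodes = 200, attachment_m = 2,
                        n_hubs = 1, hub_fraction = 0.2,
                        n_cliques = 2, clique_size = 5, seed = 42)
g <- gen$graph           # igraph object; gen$truth names the planted nodes

ct <- compute_all_centralities(g, epc_iterations = 1000, epc_seed = 43)
sc <- score_i(ct)
top_genes(sc, 5)
#>    gene    score
#> 1 G0005 888.4208
#> 2 G0049 807.5529
#> 3 G0001 694.2381
#> 4 G0014 633.1043
#> 5 G0003 589.9070

k_clique_communities(g, k = 3)
#> k-clique community set (k = 3): 13 communities covering 71 nodes
#>   9 node(s) in >= 2 communities

head(overlap_report(k_clique_communities(g, k = 3)), 3)
#>    node count
#> 1 G0049     5
#> 2 G0003     4
#> 3 G0017     3
```

Here the planted hub is `G0049` (wired to 20% of the backbone): it scores
807.6 of the possible 1000 and sits in five overlapping communities, but in
this particular draw the preferential-attachment backbone grew a natural
hub (`G0005`) that outranks it — scale-free backbones occasionally produce
their own dominant hubs, which is exactly why the score is reported as a
ranking rather than a verdict. Seed-list coverage works the same way as on
real curated lists:

```r
seed_coverage(g, c("G0001", "G0002", "NOTAGENE"))
#> seed coverage: 2/3 (66.7%)
```

A full run (DEG prefilter → seeds → network → centrality → Score I →
communities → clustering → enrichment) is one call:

```r
cfg <- pipeline_config(seed = 7, out_dir = "run1",
                       network = list(synthetic = list(n_nodes = 600)),
                       gmt = list(synthetic = list(n_sets = 40)))
run_pipeline(cfg)   # writes TSVs + manifest.json under run1/
```

## Documentation

`vignette("hub-prioritization")` describes the model, every index's
definition and conventions (components, ties, isolated nodes), the
synthetic generators and what they do and do not emulate, and the numerical
choices in the EM and permutation machinery.
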