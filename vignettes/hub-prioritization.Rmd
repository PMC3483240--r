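---
title: "Hub prioritization from PPI network topology: methods and conventions"
author: "ppihub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub prioritization from PPI network topology: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppihub)
```

## The problem and the model

Genes whose proteins occupy topologically central positions in a
protein–protein interaction (PPI) network — *hubs* — are disproportionately
likely to matter biologically. Given a disease-associated seed gene list
and a curated interaction index, the analysis implemented here expands the
seed list into its interaction neighborhood, ranks every network gene by a
composite of ten centrality indexes, and then characterizes the network's
mesoscale structure (overlapping clique communities, centrality-profile
clusters) and biological context (gene-set over-representation).

The method makes three modelling assumptions worth keeping in mind:

1. **The network is an unweighted simple graph.** Interaction confidence,
   direction and sign are discarded; duplicate records collapse to one
   edge (their provenance is retained as an edge attribute) and
   self-interactions are dropped, because all ten indexes are defined on
   simple graphs.
2. **Topological centrality proxies biological importance.** This is a
   prioritization heuristic, not a causal claim; the output is a ranking
   to be validated downstream.
3. **The interaction index is incomplete.** Seed-list coverage
   (`seed_coverage()`) and annotation coverage (reported by `enrich()`)
   are first-class outputs precisely because real indexes and gene-set
   databases miss a substantial fraction of genes.

## The ten indexes and their conventions

All shortest paths are unweighted; unordered pairs are counted once;
pair-based sums range over within-component pairs only. For a node $v$ in
a component of size $n_c$ with diameter $\Delta$:

| index | definition | isolated node |
|---|---|---|
| degree | number of neighbors | 0 |
| betweenness | $\sum_{s<t} \sigma_{st}(v)/\sigma_{st}$ | 0 |
| stress | number of shortest $s$–$t$ paths through $v$ | 0 |
| eccentricity | $1/\max_w d(v,w)$ | 1 |
| radiality | $\sum_w (\Delta + 1 - d(v,w))/(n_c - 1)$ | 0 |
| bottleneck | roots $s$ whose shortest-path tree routes $> n_c/4$ nodes through $v$ | 0 |
| MNC | size of the largest connected component of $v$'s open neighborhood | 0 |
| DMNC | edges of that component divided by its size to the power $\varepsilon = 1.7$ | 0 |
| MCC | $\sum_{C \ni v} (|C|-1)!$ over maximal cliques of size $\ge 2$ | 0 |
| EPC | mean size of $v$'s component over random edge-retention replicates | 1 |

Conventions that required a decision:

* **Eccentricity is reported as a reciprocal.** Raw eccentricity is small
  for central nodes, but the composite score rewards large values, so every
  column must satisfy "higher = more hub-like". The reciprocal (rather
  than, say, $\Delta - e(v)$) keeps values in $(0, 1]$ and is
  scale-free across components.
* **Bottleneck trees are made deterministic.** Breadth-first shortest-path
  trees are not unique; each node's parent is its lexicographically
  smallest neighbor one step closer to the root, and a node's subtree
  count includes itself. This makes results reproducible, at the price
  that on graphs with many tied shortest paths (e.g. even cycles) the
  tie-break direction is visible in the per-node values.
* **DMNC ties.** When two neighborhood components tie in size, the one
  with more edges is used (the denser candidate), which makes the index
  well defined without randomness.
* **EPC** retains each edge independently with probability 0.5 (a
  maximally uninformative perturbation) for 1000 replicates by default,
  under a caller-supplied seed; values are averages in $[1, n]$ and are
  bit-reproducible for a fixed seed. The per-node Monte-Carlo error decays
  as $1/\sqrt{T}$, and T = 1000 keeps it well below the resolution that
  the 0–100 normalization can express for networks of a few thousand
  nodes.

Stress and the shortest-path counts are computed by a level-wise dynamic
program on each source's shortest-path DAG (forward path counts, backward
continuation counts), which is algebraically identical to explicit path
enumeration — the test suite checks all ten indexes against brute-force
path/subset enumeration oracles on several hundred random graphs.

## The composite score

Each index column is min–max normalized to $[0, 100]$ over **all** network
nodes (the whole network is ranked first; restriction to a seed list
happens only when reporting top genes, so the normalization population does
not depend on the seed list). The composite score is the row sum, bounded
by $100 \cdot N_c = 1000$ for the ten standard indexes. A constant column
(max = min) is defined to contribute 0 for every node: a degenerate index
carries no ranking information, and any other convention would add an
arbitrary common offset. Ranking ties are broken lexicographically by gene
symbol for determinism.

## Communities, clustering, enrichment

**Clique percolation.** A $k$-clique community is the union of all
$k$-cliques reachable through "share $k-1$ nodes" adjacency; percolation
runs over all $k$-cliques (enumerated as $k$-subsets of maximal cliques),
not only maximal ones. The default $k = 3$ is the smallest value that
yields non-trivial overlapping modules and is the standard choice for
sparse PPI networks; larger $k$ rapidly empties sparse graphs. Communities
and their order of presentation are fully deterministic (sorted node sets,
size-then-lexicographic order).

**Model-based clustering** runs on the *normalized* centrality columns
(0–100 percentages), so no index dominates by raw scale. The
Gaussian-mixture EM supports four covariance families — spherical-equal
(`EII`), diagonal per component (`VVI`), one shared full matrix (`EEE`),
and full per component (`VVV`) — with BIC $= 2\log L - m\log n$ (higher is
better) selecting both the family and the component count over a default
range of 1–9. The fully flexible ellipsoidal family (`VVV`) stands in for
more finely constrained ellipsoidal variants (equal-volume/shape with
variable orientation), a documented simplification: with ten features and
thousands of nodes the BIC penalty difference between these variants is
small relative to component-count effects. Numerical choices: seeded
k-means initialization (5 restarts), convergence when the log-likelihood
gain drops below $10^{-6}$, at most 500 iterations, and a $10^{-6}$ ridge
on every covariance diagonal; fits whose components empty or whose
covariances remain singular are flagged and excluded from selection. The
log-likelihood trace is stored so monotonicity is verifiable per fit.
Clusters are labelled C1…CG in order of increasing mean composite score,
making "the top cluster" well defined.

**Enrichment** uses the hypergeometric upper tail $P(X \ge k)$ or, by
default, the EASE variant (the same tail with the overlap reduced by one),
which penalizes single-gene overlaps and is the conservative convention of
the standard annotation-server workflow this replaces. The default
universe is the *annotated* universe — network genes appearing in at least
one set of the collection — because mixing unannotated genes into the
background deflates p-values; the full-universe option is available, and
annotation coverage is always reported. Set classes (carried in the GMT
description column) are additionally tested as unions of their member
sets, giving disease-class-level rows. BH correction is applied within the
set table and within the class table.

**DEG prefilter.** Per gene, a two-sided label-permutation p-value on the
difference of log2 group means, $p = (1 + \#\{|T^\*| \ge |T|\})/(B+1)$,
with $B$ = 10000 when the experiment has at least 20 samples and 1000
otherwise (small designs cannot resolve finer p-values anyway; the rule is
overridable). "Resampling" wordings are ambiguous between permutation and
bootstrap; label permutation is the default because it is exact under
exchangeability, and a pooled-bootstrap variant is provided behind a flag.
Fold change is computed on linear-scale group means and filtered
symmetrically ($\max(\mathrm{fc}, 1/\mathrm{fc}) \ge 2$), while the test
statistic uses log2 values for variance stabilization. Selection requires
both the BH-adjusted p $\le$ 0.05 and the fold-change filter. Each
experiment is analyzed independently and selected genes are unioned before
merging with external ranked gene lists (top 20 per list by default).

## The synthetic-data generator

The generator produces inputs with the statistical structure the analysis
assumes, so every stage is testable without downloads:

* **Networks**: a preferential-attachment backbone (from `attachment_m`
  isolated seed nodes, each new node attaches `attachment_m` edges to
  distinct nodes chosen proportionally to degree, uniformly while all
  degrees are zero), giving $m(n-m)$ edges and the heavy-tailed degree
  distribution characteristic of PPI networks. Planted hubs are extra
  nodes wired to a stated fraction of backbone nodes; their labels are
  drawn from random positions of the shared gene-symbol namespace so that
  lexicographic tie-breaks cannot systematically favor or disfavor them.
  Planted cliques make disjoint uniform samples of backbone nodes pairwise
  adjacent. An Erdős–Rényi backbone is available for experiments that need
  a homogeneous sparse background (e.g. planted-clique recovery).
* **Gene sets**: uniform samples from a universe, with one designated set
  (sized at the top of the size range) over-sampled into the designated
  query at a stated fraction.
* **Expression**: log-normal multiplicative noise at a stated coefficient
  of variation around group means; spiked genes have an exact population
  fold change, alternating up/down. Defaults (10 vs 10 samples, CV 0.1,
  fold change 4, 5% spiked genes) mirror a typical two-group case/control
  microarray comparison.

What the generator does **not** emulate: correlated noise and batch
effects in expression data, degree-dependent annotation bias in gene-set
collections, false-positive and study-bias edges in interaction indexes,
and the mixture of curation sources of a real interaction database.
Passing tests on synthetic data therefore demonstrate algorithmic
correctness and statistical calibration under the stated generative
assumptions — not robustness to the artefacts of real curated data.

## Determinism and seeds

Every stochastic step (EPC, permutation tests, k-means initialization, all
generators) takes an explicit seed and restores the RNG state afterwards.
The pipeline derives per-stage seeds from one master seed by fixed offsets
(EPC +1, clustering +2, DEG +3, synthetic network +4, synthetic gene sets
+5, synthetic expression +6), so any stage can be rerun in isolation and
two runs with the same configuration are byte-identical.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise the pipeline at sizes
chosen to make planted structure unambiguous while keeping runs desk-scale:
oracle comparisons on exhaustive 4-node and random 5–12-node graphs,
planted-hub runs on 500-node backbones (50 and 20 replicates), planted
cliques on 300-node sparse backgrounds (20 replicates), 200–250-gene
expression matrices, and mixtures of 120–200 observations. These are
package choices, not statements about the method's scaling limits; the
implementation handles networks of a few thousand nodes comfortably.

## Known limitations

* At a planted-hub wiring fraction of 20% on a 500-node preferential-
  attachment backbone, the backbone's own heavy-tailed growth occasionally
  produces a natural hub of comparable degree and better local
  embeddedness (its neighbors interconnect; a planted hub's uniform
  neighbors mostly do not), so the planted hub is not guaranteed the top
  rank in every draw — the acceptance script reports the observed top-1
  rate rather than assuming it.
* EPC is Monte-Carlo: two analyses agree only if they share the seed.
* The clique enumeration underlying MCC and percolation is exponential in
  the worst case; PPI-scale sparse graphs are unproblematic, but dense
  graphs with thousands of nodes are outside the intended regime.
* The permutation test assumes exchangeability of samples across groups
  (no covariates, no pairing); matrices must arrive pre-normalized.
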