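---
title: "Methods: co-expression modules and multilayer network walks in cnmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and multilayer network walks in cnmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cnmnet implements two complementary analyses for multi-omics studies of
centronuclear myopathy (CNM) mouse cohorts: a weighted gene co-expression
analysis that relates expression modules to phenotypic traits, and a
multiplex-heterogeneous multilayer network explored by random walk with
restart (RWR). This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic benchmarks do and do
not establish.

## The co-expression model

Raw counts are filtered (a gene must exceed `min_count = 10` reads in at
least `min_fraction = 90%` of samples) and normalized by median-of-ratios
size factors: sample $j$'s factor is the median over genes $i$ (with
all-nonzero counts) of $c_{ij} / (\prod_j c_{ij})^{1/n}$, followed by a
$\log_2(x+1)$ transform. This is the standard bulk RNA-seq normalization
model — it assumes most genes are not differential between samples, which
is also why the synthetic generator makes non-module genes the majority.
If no gene is expressed in every sample the code falls back to
library-size factors (scaled to geometric mean 1) with a warning.

The network is **unsigned**: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with
unit diagonal. The soft power $\beta$ (dimensionless, default 12)
exponentially suppresses weak correlations while keeping the network
weighted; `pick_soft_power()` reports the scale-free fit $R^2$ across
candidate powers as a diagnostic, but the pipeline takes an explicit
power. The unsigned choice means anti-correlated genes are considered
connected, which matches module definitions that mix up- and
down-regulated processes.

The topological overlap measure combines direct adjacency with shared
neighbourhoods,
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
                          {\min(k_i, k_j) + 1 - a_{ij}},\qquad
  k_i = \sum_{u \ne i} a_{iu},$$
and $1 - \mathrm{TOM}$ is the clustering dissimilarity. Both the adjacency
and the TOM are verified in the test suite against brute-force loop
implementations to $10^{-12}$.

### Module detection: a top-down dynamic cut

Genes are clustered by average-linkage hierarchical clustering on
$1-\mathrm{TOM}$. At the feature counts this package targets (hundreds of
genes rather than the tens of thousands of a full transcriptome), TOM
values are small and the dissimilarities compress into a narrow band near
1, so any fixed quantile of the merge heights is an unstable cut. The
package therefore cuts the dendrogram top-down:

* a branch is **split** into its two children when both contain at least
  `min_module_size` (default 30) features and their branch eigengenes are
  separable — correlation dissimilarity $1 - r \ge$ `merge_threshold`
  (default 0.25). This is the exact complement of the merge criterion, so
  cutting and merging cannot oscillate;
* joins higher than `cut_height` (default 0.995, an absolute
  dissimilarity) are always descended — they attach outliers, never form
  modules;
* when a tight branch has no separable split at its root, the large child
  is searched for a deeper split before the whole branch is accepted as a
  module (outlier attachments otherwise hide genuine splits).

Features on no module branch are rescued to the module whose eigengene
they correlate with most in absolute value, if that correlation exceeds
`assign_threshold`. The default threshold is the critical correlation at
two-sided $p = 0.01$ for the available sample size (about 0.51 at $n=24$)
rather than a fixed constant: a fixed cutoff of, say, 0.3 is statistically
meaningless at small $n$ and absorbs a large fraction of null features.
Modules whose eigengenes have $1 - r <$ `merge_threshold` are then merged
iteratively (closest pair first, eigengenes recomputed after each merge;
the module count strictly decreases, so the loop terminates). Modules are
renamed with conventional colour labels in decreasing size order; `grey`
is reserved for unassigned features.

The **module eigengene** is the first right singular vector of the
feature-wise z-scored module submatrix, scaled to unit norm, with its sign
chosen so that it correlates non-negatively with the module's mean
z-profile (so negating the data negates the eigengene). A single-feature
module's eigengene is that feature's z-profile.

### Module–trait statistics and classification

Each eigengene is correlated with each trait on pairwise-complete samples
(Pearson $r$; missing trait values allowed, $n$ reported per pair). The
p-value uses $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom,
and the Bonferroni adjustment is over the number of traits:
$p_{adj} = \min(1, p \times n_{traits})$. Constant traits produce rows
with missing statistics rather than errors.

A module is **beneficial** when it has at least one significant
($p_{adj} < 0.05$) positive correlation among the functional-improvement
traits (normalized TA mass in mg/g body mass, maximal specific force
relative to wild type, hanging time in seconds) and/or a significant
negative correlation among the pathology traits (percentages of fibers
with central nuclei, abnormal mitochondria, small diameter), with no
significant correlation of the opposite pattern; **pathogenic** is the
mirror; anything else is unclassified. Classification depends only on the
signs of significant correlations, so it is invariant to row and column
order.

Thresholded co-expression layers are exported with one undirected edge per
pair whose TOM exceeds the threshold (weight = TOM). The shipped presets
are transcriptomic (power 10, threshold 0.15), proteomic (12, 0.25) and
metabolomic (5, 0.05). The literature phrasing for these exports is
ambiguous about whether the threshold applies to the TOM or to the raw
adjacency; the package applies it to the TOM, the matrix actually
computed in that step.

## The multilayer model and the walk

A `cnm_network` holds multiplexes — each an ordered list of layers over
one node type, with an explicit node universe so isolated nodes are
representable (tissue nodes, for instance, carry no tissue–tissue edges
and enter only through bipartites) — and bipartites linking multiplex
pairs, optionally directed (metabolite-to-reaction and
reaction-to-metabolite links are walked only in their stated direction).
Node identity is exact, case-sensitive string match after whitespace
trimming. Duplicate edge records collapse keeping the maximum weight
(conservative for thresholded similarity layers); self-loops are dropped.

Network summaries report one row per layer and bipartite with density
$m / \binom{n}{2}$ rounded to three decimals, applied uniformly —
including to directed layers. This single convention reproduces the
published gene co-expression, metabolite co-expression and reaction layer
densities of the reference network composition to three decimals and
satisfies the phenotype layer's `<0.001` bound; the published
protein–protein interaction row does not match this (or any standard)
formula, which we treat as a reporting discrepancy in the source table.
Bipartite rows report the combined node count and no density, since the
per-side split is not part of the summary.

The walk operates on supra-states (multiplex $k$, layer $\alpha$, node
$i$). One step factorizes as:

1. choose a multiplex: uniformly over the current multiplex and every
   multiplex where node $i$ has at least one bipartite neighbour (a custom
   row-stochastic jump matrix is accepted; mass aimed at unreachable
   multiplexes is reallocated to staying, keeping columns stochastic
   without inventing teleportation);
2. staying: pick one of the multiplex's layers uniformly (including the
   current one), then follow an out-edge of $i$ with probability
   proportional to edge weight;
3. jumping: follow a bipartite edge proportionally to its weight and land
   in a uniformly chosen layer of the target multiplex;
4. mass that lands where $i$ has no out-edges is *dangling* and is
   redirected to the restart vector, the standard PageRank correction.

With restart probability $r = 0.7$ the scores solve
$s = (1-r)(Ms + d^\top\! s\, v) + r v$, iterated until the L1 change drops
below `tolerance` ($10^{-10}$ by default; at $r = 0.7$ the iteration
contracts by 0.3 per step, so convergence takes ~20 iterations). The
restart vector $v$ places uniform mass on the seeded multiplexes
(renormalized if a multiplex has no seed), splits it among that
multiplex's seeds proportionally to seed weight, and uniformly across its
layers. Per-node scores are the **sum** of the node's supra-scores
(max-aggregation would break probability conservation); they sum to 1 and
`exact_scores()` provides a dense linear solve used as an oracle for
networks up to ~2000 supra-states. Rankings sort by score descending with
ties broken by node id ascending, so all results are deterministic.

## The hub-detection null

Seed-based rankings are dominated by topologically central nodes
regardless of the seed. The null scan draws `n_iterations` single-gene
seeds uniformly **with replacement** from a seed pool (with replacement so
the iteration count may exceed the pool size), runs one walk per seed, and
counts per category how often each node enters the top-10/50/100 of its
category. The seed is excluded from its own ranking — a seed trivially
tops its own list and would corrupt the null; whether the original
procedure did this is not documented, so the choice is flagged here.
Nodes in the top 50 in strictly more than 5% of iterations ("more than
5%", so a count of exactly 5% is not called) are nonspecific hubs; hub
removal applies to gene and metabolite categories. `full_vs_subset_scan()`
repeats the scan with the same seed sequence on the network minus chosen
layers (e.g. the experimental co-expression layers) and pairs the counts,
with a Pearson correlation per category and level.

The rule has an intrinsic scale requirement: summed over nodes, top-$k$
counts equal $k \times$ iterations, so the mean top-50 occupancy of a gene
is $50 / n_{genes}$, and the 5% cutoff is only a meaningful null when the
candidate pool is much larger than 1000 genes. The shipped
`hub_benchmark_spec()` therefore uses 3000 gene nodes (mean occupancy
1.7%) with two gene layers, a 400-node metabolite multiplex, an
ontology-like phenotype DAG, and one planted hub wired to half of the gene
nodes in every gene layer. The acceptance suite runs 20 scan replicates of
200 iterations each: the planted hub must be called in at least 19, a
median-degree gene in at most 1.

## What the generators emulate — and what they do not

`simulate_expression_with_traits()` emulates the cohort structure of the
reference study: four experimental groups (wild type, disease model,
treated wild type, treated disease model) of 6 mice; three planted modules
of 50 genes driven by latent factors with per-group offsets (disease up,
disease down, group-neutral); 300 background genes; negative-binomial
counts (dispersion 0.1, a typical bulk RNA-seq value) around
$\log_2 \mu = \log_2(\text{baseline}) + \text{effect}\cdot f + N(0, sd)$
with per-sample library factors; and seven traits built as
$\rho$-correlated transforms of their module's factor, then **averaged
within group** — reproducing the granularity limitation of studies where
phenotypes are only available as group means, so the module–trait tests
exercise exactly that statistical regime (a warning reports the achieved
correlation when averaging destroys the target $\rho$). Module loadings
mix signs (70% positive by default): all-one-signed modules would bias the
median-of-ratios size factors and imprint the factors on every gene. The
default effect size of 2 puts the realized within-module $\log_2$
correlation near 0.9 — a strong co-expression module — after the
count-sampling noise, which adds substantially to the nominal `noise_sd`.

The generators do **not** emulate: library-composition artifacts beyond
global scaling, batch effects across cohorts, count outliers, overlapping
or nested modules, realistic metabolic stoichiometry, ontology semantics,
or degree distributions of curated interaction databases (layers are
Erdős–Rényi apart from planted hubs; the phenotype layer is a random DAG
with child-to-parent edges). Passing the planted-structure benchmarks
therefore shows the algorithms are implemented correctly and are sensitive
under the stated noise model — not that real CNM data would yield modules
or hubs of any particular size or identity. Reproducing the published
module counts or node lists would require the original deposited datasets
and database snapshots and is out of scope.

## Numerical choices and problem sizes

* Solver tolerance $10^{-10}$ (L1), iteration cap 1000; non-convergence is
  an error carrying the last residual, and failed scan iterations are
  excluded from hub-rule denominators.
* Dense-oracle guard at 2000 supra-states; the acceptance toys stay below
  200 states.
* Ranking tie-break: node id ascending. Duplicate edges: maximum weight.
  Zero-variance features: correlations set to 0 with a warning.
* Acceptance problem sizes, chosen to exercise each property in seconds on
  one CPU: 50 random heterogeneous toys for solver-oracle agreement; 20
  simulations (3×50 genes, 24 samples) for module recovery (adjusted Rand
  index > 0.9 expected in ≥18); 1000 permuted-trait nulls for the test
  size (raw $p<0.05$ in 3–7%); 20 hub-scan replicates of 200 iterations on
  the 3000-gene benchmark; and a two-run pipeline determinism check
  (identical output checksums).

## Known limitations

* The dynamic-cut approximation is tuned for planted-block structure at
  hundreds of features; on full transcriptomes the established
  implementations of dynamic tree cut remain the reference.
* Bonferroni over traits is conservative when traits are highly
  correlated, as group-averaged traits typically are.
* Group-averaged traits make samples within a group statistically
  dependent; the t-test treats them as independent, exactly as in the
  source procedure. The permutation check in the acceptance suite verifies
  the empirical size of the test under this regime.
* The RWR factorization (multiplex → layer → edge, with reallocation of
  unreachable jump mass) follows the "uniform" description of the original
  method; other published parameterizations may distribute jump mass
  differently, so scores are comparable within this package rather than
  bit-identical to other implementations.
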