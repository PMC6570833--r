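---
title: "Methods: from case-control SNP panels to ranked pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from case-control SNP panels to ranked pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaspathnet)
```

`gwaspathnet` chains five analysis stages: allelic association testing,
protein-association network construction, centrality-based protein and
pathway ranking, graph clustering, and set-level comparison. This vignette
explains each stage's model, its tunable parameters, the numerical choices
behind the implementation, and what the synthetic-data generators do and do
not emulate.

## Allelic association

The unit of analysis is the 2×2 allele-count table of a biallelic SNP in an
affected versus unaffected group: `a` copies of allele 1 (by convention the
minor allele) and `b` of allele 2 among affected, `c` and `d` among
unaffected. Missing genotypes are excluded before counting, so per-SNP
effective sample sizes differ — which is also why χ² statistics cannot be
recovered from rounded allele frequencies plus nominal cohort sizes,
whereas odds ratios can (they are invariant to the allele total). The test
is the 1-df Pearson statistic without continuity correction; the p-value is
the χ²₁ upper tail, identical to `2(1 − Φ(√x))`. The odds ratio is the
literal cross-product quotient; with a zero cell it is reported literally
(0, `Inf`, or `NaN` for 0/0) with undefined CI bounds, matching how such
rows are conventionally printed, and a Haldane 0.5-correction mode is
available by flag rather than silently applied.

Quality control keeps a SNP iff its missing rate is ≤ 5%, its minor allele
frequency (over all samples) is ≥ 1%, and the Hardy–Weinberg exact test in
the *control* group has p ≥ 1e-6. These thresholds are the conventional
GWAS defaults; all three are arguments of `qc_filter()`. HWE is tested in
controls only because deviation in cases can be a genuine disease signal,
while deviation in controls indicates genotyping error. The exact test
conditions on the observed allele counts and sums the probabilities of all
heterozygote counts whose conditional probability does not exceed that of
the observed configuration; probabilities are computed on the log scale
(`lfactorial`) and renormalized, and "does not exceed" uses a relative
tolerance of 1e-12 so that ties in the discrete distribution are included
deterministically.

Significance filtering uses the raw p ≤ α (default 0.05) — deliberately no
multiple-testing gate, since the downstream network stages are exploratory
and the tested panels are small preselected candidate sets; a
Benjamini–Hochberg column is emitted for information. Results sort by
ascending p with ties broken by rsID.

## Protein-association networks

Risk genes (the loci carrying significant SNPs) map to canonical protein
symbols through an optional alias table; unmapped genes are kept under
their own symbol and reported, never silently dropped. The interaction
table is thresholded at combined score ≥ 0.400, the conventional
medium-confidence cutoff. Network expansion adds at most 20 first-shell
interactors (non-seed proteins adjacent to ≥ 1 seed) and then at most 10
second-shell interactors (proteins adjacent to ≥ 1 first-shell node).
Because the interactor-priority score used by interaction databases is not
reproducible offline, candidates are ranked by the *sum of edge confidences
to the current network* — a monotone, deterministic surrogate for
"most strongly attached first" — with ties broken by protein symbol. All
qualifying edges among included nodes are materialized and nodes left
without any edge are removed, so the final graph never contains isolated
nodes. Shell selection is shell-first (fill shell 1 to its cap, then
shell 2), not a global top-30.

Edge confidences are retained as weights for display and for MCL, but
centralities are computed on the unweighted topology: there is no
principled conversion of a confidence into a path length, and an optional
distance mode (d = 1 − score) is the flag-guarded alternative.

## Centrality scoring and ranking

Three node centralities are computed: degree `deg(v)/(n−1)`, Latora
harmonic closeness `(1/(n−1)) Σ 1/d(u,v)` (with `1/∞ = 0`, which is the
reason harmonic closeness is preferred over classic closeness — it is
well-defined on disconnected graphs), and betweenness normalized by
`(n−1)(n−2)/2`. Each centrality column is min–max rescaled to [0, 1]
across the network's nodes before weighting; the rescaling is what lets
the fixed 0.2/0.3/0.5 weights act on comparable scales, and a constant
column maps to 0 rather than propagating a 0/0. The combined score is

```
combined = 0.2 * deg' + 0.3 * clo' + 0.5 * bet'
```

with betweenness weighted heaviest, reflecting the view that bottleneck
proteins carry the most functional information in association networks.
A raw-scale mode (`rescale = FALSE`) exists for sensitivity analysis.
Rankings are descending by combined score, ties broken by symbol, so the
whole stage is deterministic. Pathway ranking averages the combined scores
of each gene set's *contributing* proteins — members present in the
analyzed network — not the full set membership, so a pathway is judged by
the topological importance of the proteins that actually appear.

## Clustering

**MCL.** The protein network is clustered by the Markov Cluster Algorithm
with inflation 3: self-loops of weight 1 are added (canonical practice,
preventing period-2 oscillation), the adjacency is column-normalized, and
expansion (matrix square) alternates with inflation (entrywise power then
renormalization). Entries below 1e-5 are pruned each iteration;
convergence is declared when the largest entry change falls below 1e-8,
with a 200-iteration cap that raises an error reporting the residual
rather than returning a half-converged partition. Clusters are read from
attractor rows and overlapping attractor systems are merged. Because only
the graph itself is available offline, MCL runs on the (confidence-
weighted) adjacency rather than any database-internal similarity — a
documented divergence from service-side clusterings, whose exact cluster
counts are therefore out of scope.

**Girvan–Newman.** Pathway networks are clustered by iterative removal of
the edge with maximal edge betweenness, ties broken by lexicographic
endpoint pair, returning the partition along the removal sequence that
maximizes Newman–Girvan modularity of the original graph. Edgeless input
yields singletons, and communities never span disconnected components.

## Enrichment and complementary pathway networks

Over-representation of a query gene list in a gene-set database is scored
by the hypergeometric upper tail `P(X ≥ k)` against a background defaulting
to the union of all database genes; sets with zero overlap are excluded,
ranking is by ascending p with ties by larger overlap then set id, and the
top 10 sets become seeds. BH adjustment is reported but not used for seed
selection — seeding is a fixed-size "top ten", not a significance cutoff.
Service-side combined scores (log-p × rank deviation) need precomputed
background ranks and are not reproducible offline.

The pathway scaffold links two database sets when the Jaccard index of
their member lists is ≥ 0.05 — an offline surrogate for curated
pathway–pathway relation maps; 0.05 keeps pathway pairs with a clearly
non-incidental gene overlap while not connecting everything to everything.
Complementary-network construction starts from the scaffold subgraph
induced on the seeds and greedily adds the shortest scaffold path (fewest
new intermediates; ties by larger summed Jaccard weight, then
lexicographic path) between two seed components until one component
remains or no connecting path exists. A final pruning pass removes any
added pathway whose removal does not disconnect the network, so every
retained complementary pathway is a cut node — the minimality the
construction promises. If seed components are genuinely unreachable the
function warns and returns the partial network rather than failing.

## Set comparisons and disease networks

Venn regions are computed exactly for 2–4 named lists (beyond 4 a Venn
diagram stops being interpretable; the function refuses), and the region
family is asserted to partition the union on every call. The
method-consensus merge is plain set algebra. The disease–disease network
operationalizes "shared molecular background" as shared pathway
identifiers: an edge requires ≥ 1 shared pathway (configurable) and is
weighted by the Jaccard index of the two pathway profiles, with isolated
diseases retained and flagged. Both the thresholded and the weighted view
are thus available to downstream consumers.

## Synthetic data: what it emulates, what it does not

`simulate_genotypes()` draws each genotype as Binomial(2, f) — HWE within
each group — with the case frequency derived from the control frequency
and a target allelic odds ratio by `f_A = OR·f_U / (1 − f_U + OR·f_U)`,
and masks calls completely at random. `table2_sim_spec()` turns the
packaged association table into such a spec, so simulated cohorts mirror
the published panel's frequencies and effect sizes. Planted HWE violations
for QC tests are injected as explicit genotype counts (e.g. all
heterozygotes), since frequency perturbation alone cannot break
within-group HWE. The generator deliberately omits linkage disequilibrium,
population stratification and genotype-calling error; passing tests
therefore demonstrate correctness of the statistics under the model's own
assumptions, not robustness to confounding in real cohorts.

`simulate_ppa()` builds planted-partition graphs (within-module edge
probability 0.8, between 0.02, mirroring the density of small
disease-module networks) with within-module confidences above the 0.400
threshold and a configurable fraction of between-module confidences below
it, so thresholding behaves as it does on real interaction dumps.
`simulate_genesets()` plants one set with an exact k-gene query overlap
while capping all background sets at ≤ 1 shared gene, giving
over-representation tests an unambiguous ground truth. All generators
save and restore the global RNG state, so they are pure functions of their
seed argument.

## Problem sizes and numerical tolerances in the test suite

The suite cross-checks every statistic against an independent brute-force
oracle: centralities against exhaustive simple-path enumeration on 1,000
random graphs of ≤ 7 nodes; the hypergeometric tail against direct
mass-function summation for backgrounds ≤ 60; the HWE exact test against
full enumeration over genotype configurations for totals ≤ 50; MCL against
planted 4×10-module partitions (20 seeds, mean adjusted Rand index);
type-I error on a 10,000-SNP null panel at 200/200 samples; and odds-ratio
recovery over 200 replicates at 5,000/5,000. Exact identities use
tolerances of 1e-9 to 1e-12; simulation-based checks use the interval
[0.04, 0.06] for the 5% type-I error and < 2% relative bias for OR
recovery. These sizes make the full suite run in well under a minute while
keeping every Monte-Carlo margin wide relative to its standard error.

## Known limitations

- Published network-level numbers (node/edge/cluster counts, specific
  protein and pathway rankings) depend on interaction/pathway database
  snapshots and are not reproducible offline; the package reproduces the
  *procedures* and verifies them on synthetic ground truth instead.
- The shell-expansion ranking and the complementary-network connection
  rule are documented surrogates for service-internal algorithms, chosen
  for determinism, not claims about those services' internals.
- The association stage implements the allelic test only — no covariate
  adjustment, imputation or stratification correction, which matches its
  intended use on preselected candidate panels.
- The study behind the packaged panel reports its control count
  inconsistently (441 in one place, 445 in its cohort table); the packaged
  examples use the cohort table's 445.
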