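---
title: "From counts to hub genes: the degnet methods"
author: "degnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From counts to hub genes: the degnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

`degnet` chains four analyses that usually live in four different tools:
negative-binomial differential expression, STRING-style interaction-network
construction, graph-centrality hub discovery, and hypergeometric
over-representation analysis (ORA). This vignette explains the model behind
each stage, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical corner cases.

## 1. Differential expression

### Model

Counts for gene $g$ in sample $j$ are modelled as negative binomial with mean
$s_j \mu_{gc(j)}$ and a gene-wise dispersion $\alpha_g$, so that
$\mathrm{Var} = \mu + \alpha\mu^2$. The size factors $s_j$ are the
median-of-ratios estimates: the median, over genes with positive counts in
every sample, of the sample count divided by the gene's geometric mean across
samples. Genes that fail the all-positive eligibility rule still get
normalized and reported; they just do not vote on the size factors.

The per-condition normalized means $\hat\mu_{ctrl}, \hat\mu_{trt}$ give the
effect estimate $\widehat{\mathrm{LFC}} = \log_2(\hat\mu_{trt}/\hat\mu_{ctrl})$
(positive = up under treatment). Its delta-method standard error is

$$\mathrm{SE}^2 = \frac{1}{(\ln 2)^2}\sum_{c \in \{ctrl,trt\}}
  \frac{1}{n_c}\left(\frac{1}{\hat\mu_c} + \hat\alpha\right),$$

and the Wald statistic $\widehat{\mathrm{LFC}}/\mathrm{SE}$ is referred to the
standard normal, two-sided. Benjamini–Hochberg correction across all tested
genes gives q-values; `q <= 0.05` (inclusive) defines a DEG. This is a
deliberately transparent NB test — no fold-change shrinkage, no outlier
replacement, no independent filtering — and its observable surface (the log2
ratio of normalized condition means) is exactly what the packaged
worked-example table checks: all ten published fold changes are reproduced to
two decimals by `verify_table1()` (rounding half away from zero).

### Dispersion estimation

With few replicates the method-of-moments estimator
$\hat\alpha = \max\!\big(0, (s^2-\bar m)/\bar m^2\big)$ (averaged over the two
conditions) is extremely noisy, so by default it is shrunk with fixed weight
0.5 toward a mean-expression trend (`dispersion_mode = "shrink"`). The trend
is a **rolling mean** of the gene-wise estimates along the expression
ordering (window 101 genes, shrinking symmetrically at the edges). A rolling
median may look like the more robust choice, but the sampling distribution of
$\hat\alpha$ at $n = 5$ replicates is strongly right-skewed, so a median
trend sits systematically below the true dispersion and makes the Wald test
anticonservative; with the rolling mean the empirical size at nominal 0.05
lands at 0.05–0.06 in the calibration simulations (2000 genes, 5
replicates/group, $\alpha = 0.1$), inside the 0.03–0.07 band the test suite
enforces.

Genes with a zero mean in either condition have an undefined log2 ratio.
They are flagged and excluded from testing rather than rescued with a
pseudocount: any pseudocount value would be arbitrary, and it would also
break the exact correspondence between the reported fold change and the
ratio of reported means.

### What the normal reference does and does not buy

The normal-referenced Wald p-values are well calibrated near conventional
thresholds but their extreme tail is inflated — at $n = 5$ the statistic's
tail is heavier than Gaussian, and no amount of dispersion shrinkage repairs
the far tail (we measured it: even at full shrinkage to the trend, a
2000-gene global-null run produces at least one BH-significant gene roughly
10–40% of the time, rather than the $\le 5\%$ exact uniformity would give).
Consequences for practice: single false DEGs appear under the global null at
a higher-than-nominal rate, while the *fraction* of genes falsely called
stays far below 1%, power for two-fold effects at moderate expression is
essentially 1, and the empirical FDR of the called set at `q <= 0.05` stays
near 0.1. The tests assert exactly these calibrated properties, not the
idealized ones.

## 2. The interaction network

### Channel recombination

STRING's combined score treats the evidence channels (neighborhood, fusion,
co-occurrence, co-expression, experimental, database, text mining) as
independent detectors sharing a prior $p_0 = 0.041$ that a random pair
interacts. The published combined score cannot be decomposed, so excluding
channels means **recombining** from the per-channel scores:
$s' = \max(0, (s-p_0)/(1-p_0))$ per allowed channel, $1 - \prod(1-s')$, then
re-add the prior. Two consequences drive the pipeline's behaviour and are
enforced as tests: a single allowed channel recombines to itself (to within
$10^{-3}$), and an edge supported only by excluded channels collapses to
$p_0 = 0.041$ — which is how text-mining-only edges die at the 0.900 cut.
The excluded set defaults to text mining, neighborhood, fusion and
co-occurrence (the indirect channels); the homology channel is not modelled.
The threshold comparison is inclusive (`>= 0.900`), matching the "highest
confidence" band convention, and both threshold and prior are configurable.

### Subnetwork selection and centrality

The DEG-restricted graph keeps every DEG as a vertex (isolated DEGs are
real degree-0 nodes, as in a STRING export of a gene list). Components are
ranked by diameter — the longest unweighted shortest path within the
component — and the maximum-diameter component is selected; ties break by
node count, then by the lexicographically smallest node set, so selection is
deterministic. The rationale for diameter rather than size: the most
*extended* component is where chains of signalling interactions live, while
a dense clique of co-regulated genes (ribosomal proteins being the
archetype) has diameter 1–2 no matter how large it is.

Ribosomal-protein genes — supplied as a plain gene-list file, standing in
for a curated gene-group annotation — are then removed as an induced
subgraph operation. The graph may disconnect; no re-selection happens
afterwards, so peripheral fragments of the component remain visible in the
centrality table.

Betweenness is normalized by $(n-1)(n-2)/2$ with $n$ the node count of the
graph *being analyzed* (the pruned subnetwork), endpoints excluded; this is
the only normalization under which a hub threshold of 0.5 is meaningful.
Hubs must strictly exceed both thresholds (betweenness > 0.5, degree > 2).
In components of fewer than three nodes betweenness is identically 0.

## 3. Over-representation analysis

The query (the retained subnetwork genes) is tested against each GMT gene
set with the upper-tail hypergeometric probability $P(X \ge k)$ — inclusive,
the standard ORA convention — with BH FDR across terms and fold enrichment
$(k/n)/(K/N)$. The background universe is the intersection of the genes
measured in the count matrix with the genes annotated in the collection;
this is configurable in spirit (any background can be passed to
`hypergeom_enrichment()` directly) but is the pipeline default because it is
the only universe both data sources can justify. The report filters at
FDR ≤ 0.05 and sorts by fold enrichment (ties: FDR, then term id). Term
clustering or GO-graph redundancy reduction is out of scope; the flat ranked
table is the product.

## 4. The synthetic-data generator

The generator emulates the *statistical shape* each stage assumes, with
ground truth recorded for recovery tests:

- **Counts**: NB with a single shared dispersion (default 0.1, a typical
  cell-line value), baseline means log-uniform over roughly 20–5000, size
  factors log-uniform in [0.5, 2] so normalization is non-trivial, and a
  planted DE fraction (default 10%) at $|\mathrm{LFC}| = 2$ with random
  signs. Two replicates per group is the faithful default for the emulated
  experimental design, but recovery tests run at five replicates because
  two-replicate NB testing is intrinsically under-powered.
- **Interactome**: a star-plus-chords hub cluster with a short tail path
  (the tail guarantees the cluster's component has the largest diameter,
  since a star alone has diameter 2 and could be out-diametered by chance
  background chains); a ribosomal clique attached to the component through
  one leaf; text-mining-only decoy edges; and sparse background edges whose
  experimental scores span the 0.900 threshold. Structural edges carry high
  experimental/database scores so they survive recombination.
- **Gene sets**: one planted term drawn ≥ 80–90% from a designated gene set
  (the pipeline plants it on the hub cluster, since the retained subnetwork
  is the downstream query) plus uniform random terms.

What it does **not** emulate: gene–gene count correlation, varying
dispersion–mean relationships, library-preparation artefacts, identifier
mapping noise between proteins and genes, and annotation bias in gene-set
sizes. Passing recovery tests therefore demonstrates that the pipeline's
logic is correct and calibrated under its own model assumptions — not that
real data meet those assumptions.

## 5. Numerical choices and degenerate inputs

- Determinism: every generator consumes an explicit seed; two runs with the
  same configuration and seed produce byte-identical artifacts including the
  JSON report.
- Rounding for the worked-example comparison is half-away-from-zero to two
  decimals, the convention used for the printed values.
- `pmax`/ratio arithmetic keeps all channel scores in [0,1]; inputs outside
  the range are rejected, as are priors ≥ 1.
- Empty or degenerate inputs degrade gracefully where the pipeline can
  continue (a null run with zero DEGs reports empty network sections; a
  query with no annotated gene skips ORA) and fail loudly where it cannot
  (no all-positive gene for size factors, fewer than two replicates,
  malformed GMT lines reported with their line number).
- Simulation scale in the shipped tests (hundreds to 2000 genes, 60–300
  Monte-Carlo repetitions) was chosen as the smallest scale at which the
  asserted proportions are stable to the tolerances tested; the same
  properties hold at larger scale.

## 6. Known limitations

- The DE stage is a simplified NB Wald test; at very small counts or with
  outlier replicates a full GLM framework with outlier handling will behave
  differently.
- The betweenness normalization matches the analyzed-graph node count; when
  comparing hub lists across differently sized subnetworks the 0.5 threshold
  is not transferable.
- ORA treats gene sets as flat and independent; hierarchically related terms
  will co-appear in the report.
- The pipeline assumes symbol-keyed interactions; no identifier mapping is
  performed.
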