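# degnet

Network transcriptomics for two-condition bulk RNA-seq: from a raw count
matrix to differentially expressed genes (DEGs), to a confidence-filtered
protein–protein interaction network over those DEGs, to the hub genes of its
most extended subnetwork, to the biological processes they over-represent.

The workflow mirrors a common systems-biology analysis of a treated-vs-control
neuronal model: call DEGs with a negative-binomial test, build a STRING-style
interaction network restricted to the DEGs using only direct-evidence
channels at the highest confidence band, focus on the subnetwork with the
largest diameter, strip out the ribosomal-protein cluster that otherwise
dominates it, rank the remaining nodes by degree and betweenness centrality,
and run over-representation analysis on what is left. A seeded synthetic-data
generator plants every structure the pipeline is supposed to find — DE genes
with known signs, a hub cluster, a ribosomal clique, text-mining-only decoy
interactions, and an enriched gene set — so the whole chain is testable
against ground truth.

## The statistics inside

**Differential expression.** Counts are normalized with median-of-ratios size
factors: `s_j = median_g ( c_gj / (prod_k c_gk)^(1/m) )` over genes positive
in every sample. Per gene, the NB dispersion α (variance `μ + αμ²`) is
estimated by the method of moments within each condition,
`α̂ = max(0, (s² − m̄)/m̄²)`, averaged across conditions and shrunk half-way
toward a mean-expression trend. The Wald statistic is

```
z = log2(μ̂_trt / μ̂_ctrl) / SE,   SE² = (1/ln 2)² Σ_cond (1/n_cond)(1/μ̂_cond + α̂)
```

with a two-sided normal p-value and Benjamini–Hochberg correction; genes with
`q ≤ 0.05` are DEGs.

**Network.** STRING evidence channels are recombined after removing the
shared prior `p₀ = 0.041`: each allowed channel score becomes
`s' = max(0, (s − p₀)/(1 − p₀))`, the channels combine as `1 − Π(1 − s')`,
and the prior is re-added. Text-mining, neighborhood, fusion and
co-occurrence channels are excluded by default; edges need a recombined score
≥ 0.900 and two DEG endpoints. Betweenness is computed over unweighted
shortest paths (Brandes), endpoints excluded, normalized by `(n−1)(n−2)/2`;
hubs must have betweenness > 0.5 **and** degree > 2 (strict).

**Enrichment.** For a query of n genes against a set of K genes in a
background of N, the p-value is the hypergeometric upper tail `P(X ≥ k)`,
FDR is BH across terms, fold enrichment is `(k/n)/(K/N)`, and the report is
sorted by fold enrichment after filtering at FDR ≤ 0.05.

## Worked example

```r
library(degnet)

cfg <- run_config(
  sim  = sim_config(n_genes = 1200, n_reps_per_group = 5, de_fraction = 0.1,
                    effect_log2 = 2, dispersion = 0.1,
                    mean_log_range = c(log(100), log(5000))),
  seed = 3
)
rep <- run_all(cfg)
print(rep)
```

```
[simulate] 1200 genes, 10 samples, 120 planted DE, 363 edges, 50 gene sets
[deg] 135 DEGs (58 up, 77 down) of 1200 genes tested
[network] 135 nodes, 43 edges, avg degree 0.637, avg clustering 0.082
[component] selected 21-node component with diameter 6
[prune] removed 8 group nodes, 13 DEGs kept
[hubs] 1 hub nodes (betweenness > 0.5, degree > 2): G01187
[ora] 1 terms pass FDR <= 0.05; top term: TERM0001
pipeline report (schema 1.0, seed 3)
  DEGs: 135 (58 up, 77 down)
  ...
  truth: hub recovered=TRUE, planted term rank=1, decoys in network=0
```

Reading the output: of 1200 simulated genes, 135 pass BH at 0.05 (the 120
planted DE genes plus a controlled number of false calls). The DEG network
keeps only direct-evidence edges at combined score ≥ 0.900, its
highest-diameter component has 21 nodes, the 8-gene ribosomal clique is
removed leaving 13 genes, the planted hub is the only node passing both
centrality thresholds, and the planted gene set ranks first in the
enrichment report. Text-mining-only decoy edges never enter the network —
stripped of the excluded channels their score collapses to the 0.041 prior.

The package also ships a published worked-example table of ten
DNA-damage-response genes (normalized condition means and printed log2 fold
changes); `verify_table1()` recomputes every fold change from the printed
means and confirms all ten rows to two decimals.

A thin command-line front end over the same functions is in
`inst/scripts/degnet-cli.R` (subcommands `simulate`, `deg`, `network`,
`ora`, `run-all`, `verify-table1`).

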