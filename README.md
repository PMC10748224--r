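# hrrgcn

Gene co-expression network analysis for staged bulk RNA-seq experiments,
built around **highest reciprocal rank (HRR)** edge ranking and **Markov
clustering (MCL)**. The package is aimed at researchers studying staged
developmental processes (its defaults mirror a seven-stage flower-development
design: VS, FI, FM, BS-1, BS-2, BS-3, FS) who want to go from an FPKM matrix
and a differential-expression table to stage-associated gene modules, hub and
key genes, and transcription-factor subnetworks — with every step scriptable
and reproducible.

## The method

Given an expression matrix *X* (genes × samples, FPKM semantics) with stage
metadata:

1. **Expressed-gene filter** — keep genes with FPKM ≥ 2 in at least one
   stage-mean transcriptome.
2. **Candidate screen** — from a per-comparison DEG table, keep genes with
   FDR ≤ 0.05 and |log₂FC| ≥ 1 in any adjacent-stage comparison (plus any
   curated extras).
3. **HRR network** — compute Pearson *r* over replicate-level samples.
   For each gene rank all partners by |r| (rank 1 = strongest), and set
   HRR(A,B) = max(rank_A(B), rank_B(A)). Keep an edge when |r| ≥ 0.8 **and**
   HRR ≤ 30 (both inclusive); edges carry *r*, HRR, a weight (1/HRR), and a
   sign.
4. **MCL clustering** — alternate expansion (matrix squaring of the
   column-stochastic flow matrix) and inflation (entrywise power *I* = 3 with
   renormalisation) until convergence; attractor systems define clusters.
5. **Cluster filter** — hypergeometric over-representation of annotation
   terms per cluster (BH-FDR within each cluster's term family); drop
   clusters with fewer than 3 genes or no significant term
   (FDR < 0.05, ≥ 2 genes on the term).
6. **Modules** — merge clusters whose eigenprofiles (mean member z-scored
   stage profiles) correlate at ≥ 0.9, by average-linkage clustering.
7. **Hubs and key genes** — rank intramodular connectivity (sum of 1/HRR
   edge weights within the module); top 10 are hub genes, the top-ranked one
   is the module's key gene.
8. **TF subnetwork** — connect each key gene to every transcription factor
   with |r| ≥ 0.8.

A seeded synthetic generator plants module structure (stage-peaked
archetypes, hub genes with tighter profile adherence, enriched annotation
terms, TF labels) so the entire pipeline can be exercised and benchmarked
against known ground truth without external data.

## Worked example

```r
library(hrrgcn)

ds  <- generate_gcn_dataset(seed = 1)   # 10 planted modules x 20 genes + 100 background
fit <- hrr_gcn(ds$expression, deg = ds$deg,
               annotation = ds$annotation, tf = ds$tf)
fit
#> HRR gene co-expression network
#>   300 genes -> 300 expressed -> 200 candidates
#>   network: 193 nodes, 1722 edges (|r| >= 0.8, HRR <= 30)
#>   clusters: 11 (MCL, I = 3), 11 kept after filtering
#>   modules: 10, key genes: 10, co-expressed TFs: 26
```

The funnel reads: all 300 simulated genes are expressed, 200 pass the DEG
screen, 193 of them are connected in the HRR network, MCL finds 11 clusters
(one planted module splits), all survive the enrichment filter, and profile
merging reassembles exactly 10 stage-ordered modules. Each module reports a
key gene and its hub list:

```r
summary(fit)      # topology report, per-module composition, key genes
plot(fit)         # module mean z-profiles across the seven stages
coef(fit)[["1"]]  # intramodular connectivity ranking of module 1
```

Against the planted truth, the recovered module assignment has adjusted Rand
index 0.945 and 9 of the 10 planted hub genes appear in their module's hub
list (seed 1). File-driven runs use a YAML config:

```r
simulate_gcn_dataset("data", seed = 1)
run_gcn_pipeline(gcn_config(expression = "data/expression.tsv",
                            deg = "data/deg.tsv", gmt = "data/annotation.gmt",
                            tf = "data/tf.tsv"), out_dir = "out")
```

which writes the network (SIF/GraphML), topology JSON, cluster/module TSVs,
enrichment table, hub report, TF subnetwork, and a manifest with input
hashes and the full count funnel. Identical config + seed reproduces every
artifact byte for byte.

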