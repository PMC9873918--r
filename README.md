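# colitraj

Temporal signatures of experimental colitis from time-course RNA-seq.

Murine colitis models (DSS hit/rest cycles, adoptive T-cell transfer) are
sampled at fixed sacrifice days; the scientific question is which
transcriptional changes are *fixed* (present at a given day), which are
*dynamic* (the disease-vs-control difference itself changes over time), how
splicing changes relate to expression changes, how the adaptive immune
compartment expands, and whether signatures built from all of this predict
histopathological severity across cohorts, tissues, models — and, via
orthologs, in human IBD.

`colitraj` implements that pipeline end to end for gene- and exon-level
count matrices with sample metadata (group, day, cohort, tissue):

* **Fixed signatures** — disease vs control at one day. Engine `nbglm` fits
  per-gene negative-binomial log-linear models, μ = L·exp(β₀ + x·δ), with
  trend-shrunk Pearson dispersions and a Wald t-test on the group
  coefficient; engine `wlm` runs a log₂-CPM transform with mean–variance
  precision weights, per-gene weighted least squares, and empirical-Bayes
  moderated t-statistics (posterior variance (d₀s₀² + d s²)/(d₀ + d)).
  Signatures apply the rule logFC > 0 at FDR ≤ 0.05 (direction and
  thresholds configurable).
* **Dynamic signatures** — a likelihood-ratio test of
  `group + day + group:day` against `group + day` (shared per-gene NB
  dispersion, χ² with days − 1 df), then fuzzy c-means (memberships
  U ∝ (1/d²)^(1/(m−1)), fuzzifier 1.25, k = 5) on standardized median
  disease trajectories, with clusters labeled by canonical temporal classes
  (A early, B late, C very-early, D day-12-up, E day-12-down).
* **Differential exon usage** — each exon's coefficient minus the
  inverse-variance gene average, moderated t per exon, Simes and moderated-F
  gene aggregation, flagged at FDR < 0.10 by either route (trajectory
  variant at FDR < 0.05); isoform-specific expression and co-correlated
  gene lists (Pearson r > 0.8).
* **VDJ scores** — reads at immune-receptor loci per million library reads,
  and clonality 1 − H/ln K (normalized Shannon entropy of clone
  frequencies).
* **Histology prediction** — per sample: 3 signature PCs for genes, 3 for
  relative exon usage, median scores of both, VDJ burden and clonality;
  a 500-tree random forest with 10-fold cross-validated feature retention,
  validated on held-out cohorts by Spearman rho, Cohen's kappa and top-3
  permutation importances (validation cohorts are projected with training
  loadings, never refit).
* **Human translation** — ortholog projection, AIC-minimizing backward
  selection over restricted-cubic-spline expansions (3 knots) of the first
  five signature PCs, bootstrap optimism-corrected R² (300 replicates,
  selection rerun inside each), hypergeometric signature-vs-subnetwork
  overlap and first-neighbor expansion.

A negative-binomial synthetic-data generator (`sim_config()`,
`simulate_experiment()`) plants all of this structure — per-day and
persistent effects, five trajectory classes, isoform switches, severity-
linked VDJ tables and histology — with ground truth, and the test suite
verifies recovery, FDR calibration, and cross-cohort prediction against it.

## Worked example

```r
library(colitraj)

cfg <- sim_config(n_genes = 800, seed = 42)   # 2 groups x 4 days x 10 mice
sim <- simulate_experiment(cfg)

de5  <- timepoint_de(sim$gene, sim$meta, day = 5, engine = "nbglm")
sig5 <- extract_signature(de5)                # logFC > 0, FDR <= 0.05
sig5
#> signature 'fixed-day-5': 189 genes

lrt  <- interaction_lrt(sim$gene, sim$meta)
hits <- lrt$gene_id[!is.na(lrt$q) & lrt$q < 0.05]
length(hits)
#> [1] 419

we   <- logcpm_transform(sim$gene)
traj <- median_disease_trajectories(we, sim$meta,
          intersect(hits, subset(sim$truth$labels, grepl("cluster", label))$gene_id))
fc   <- fuzzy_cmeans(standardize_trajectories(traj), k = 5, seed = 1)
table(fc$letters[fc$hard])
#>  A  B  C  D  E
#> 40 40 40 40 40

sp <- splice_at_day(sim$exon, sim$annotation, sim$meta, day = 5)
sum(sp$gene$flagged)
#> [1] 30

prof <- vdj_profile(sim$vdj, sim$gene$library_sizes)
h    <- setNames(sim$histology$histology, sim$histology$sample_id)
vdj_severity_correlation(setNames(prof$vdj_read_cpm, prof$sample_id), h)$rho
#> [1] 0.65
```

The day-5 signature catches the planted day-5 and persistent effects plus
the trajectory classes active at day 5; the interaction test recovers the
200 planted trajectory genes (and the day-specific effects, which also
interact with time) while persistent genes — equally shifted at every day —
are correctly absent; the five recovered clusters map one-to-one onto the
planted temporal classes; all 30 planted isoform switches are flagged as
differential usage; and the VDJ burden tracks histological severity.

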