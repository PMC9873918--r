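---
title: "Temporal colitis signatures: models, assumptions and design choices"
author: "colitraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal colitis signatures: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`colitraj` analyses time-course RNA-seq of murine colitis models sampled at
fixed sacrifice days (default days 5, 12, 17 and 36 of a DSS hit/rest
protocol, disease vs control). It derives:

* **fixed signatures** — genes differentially expressed between disease and
  control at a single day;
* **dynamic signatures** — genes whose disease-vs-control difference itself
  changes over time (a disease-by-time interaction), soft-clustered into
  temporal classes;
* **differential exon usage** — exons whose fold change deviates from their
  gene's average fold change, aggregated to gene-level calls;
* **adaptive immune scores** — VDJ read burden per million library reads and
  clone-frequency clonality;
* **histology prediction** — a ten-term feature vector (three signature PCs
  per modality, median scores, VDJ burden and clonality) feeding a random
  forest trained on one cohort and validated on others;
* **human translation** — ortholog projection, AIC-penalized restricted
  cubic spline regression of histology indices on signature PCs with
  bootstrap optimism correction, and hypergeometric network overlap.

A negative-binomial synthetic-data generator with planted ground truth
exercises the whole pipeline; every statistical claim quoted below is
computed by the test suite or by `scripts/acceptance.R`, never asserted.

# Count models

## Log-CPM with precision weights

`logcpm_transform()` computes `E = log2((count + 0.5) / (lib + 1) * 1e6)`
and observation weights from a mean-variance trend: per-feature residual
standard deviations (on the square-root scale) are lowess-smoothed (span
0.5) against average log2 count and evaluated at each observation's fitted
log2 count; the weight is the predicted standard deviation to the power −4.
With fewer than 50 features the trend is not estimable and unit weights are
used with a warning. The weights correlate above 0.95 with an independent
implementation of the same transform on simulated data (checked in the test
suite).

## Weighted fits and variance moderation

`fit_weighted_lm()` solves a per-feature weighted least-squares problem;
residual df is `n − rank(design)` and features with zero residual df are
flagged untestable. `moderate()` shrinks residual variances toward a common
prior fitted by method of moments on `log s²` with digamma/trigamma
corrections; the prior df solves a trigamma equation by Newton inversion.
Two limits anchor the implementation: prior df 0 reproduces ordinary
t-statistics exactly, and identical residual variances are a fixed point
(infinite prior df, posterior equal to the common value). On simulated
scaled-F variances with true prior df 4 the estimate lands within 25%.

## Negative-binomial engines

Per-gene NB models use a hand-rolled IRLS (log link, fixed dispersion,
library-size offset). Dispersion is estimated by solving the Pearson moment
equation under the fitted means. Two front-ends exist:

* `timepoint_de(engine = "nbglm")` — intercept + group at one day;
  dispersions are shrunk 50% (log scale) toward a lowess mean-dispersion
  trend; the Wald statistic on the group coefficient is referred to a *t*
  with the residual df. The t reference was chosen over the normal because
  at 10 mice per group the normal tail produced measurable global-null BH
  rejections; with the t reference the rejection rate is nominal.
* `interaction_lrt()` — full model `group + day + group:day` vs reduced
  `group + day`, day a 4-level categorical factor (control and the first
  day as references). Both likelihoods are maximized at a shared per-gene
  dispersion estimated under the full model, so the statistic is
  non-negative by construction; it is referred to a chi-square with
  `n_days − 1` df. Null simulations (2,000 genes, 10/group/day) pass a
  Kolmogorov–Smirnov uniformity check on the p-values.

## Library-size normalization

Analysis entry points replace column-sum library sizes with
median-of-ratios effective sizes (`normalize_library_sizes()`) by default.
Without this, any imbalance in the direction of true changes leaks into the
fold changes of unchanged genes (composition bias); with it, planted null
genes recover a mean log-fold-change within a few hundredths of zero even
when a third of the transcriptome is perturbed. Normalization is per
matrix; blood and colon cohorts are never normalized jointly.

# Signatures

`extract_signature()` applies the headline rule — logFC > 0 with FDR ≤ 0.05
— with the direction and both thresholds exposed (`direction = "both"` is
used wherever down-regulated genes matter). `timepoint_specificity()`
reports the fraction of the signature union present at exactly one day.

For dynamic signatures, genes passing the interaction FDR are summarized by
their **median disease trajectory** (per-day median of log2-CPM over disease
samples), row-standardized, and soft-clustered by fuzzy c-means:
memberships `U_gc ∝ (1/‖t_g − c_c‖²)^(1/(m−1))` normalized per gene,
centres the `U^m`-weighted means, iterated to a centre-shift tolerance of
1e-6. The fuzzifier defaults to m = 1.25 (a data-driven estimate as a
function of the number of genes and days is available via
`estimate_fuzzifier()`); k = 5 matches the five canonical temporal classes.
Initialization is a seeded k-means++ draw with five restarts keeping the
lowest fuzzy objective — a single start occasionally split one planted
class. Cluster letters (A early, B late, C very-early, D day-12-up,
E day-12-down) are assigned by maximal correlation with canonical shape
templates, ties broken by cluster size.

# Differential exon usage

Exon-level fits reuse the weighted-LM/moderation machinery. For a tested
coefficient, `diff_splice()` forms the inverse-variance gene-average of the
exon coefficients; each exon's deviation from it is tested with a moderated
t whose variance accounts for the subtraction (`se² − 1/Σw`). Gene-level
evidence combines a Simes aggregate of the exon p-values and a moderated F
(mean squared deviation t over `n_exons − 1`); each route is BH-adjusted
and a gene is flagged when the smaller q is below 0.10 (fixed-day rule).
The trajectory variant applies the same deviation logic to the three
interaction columns, forms a per-exon F, Simes-combines within gene, and
uses FDR 0.05. Single-exon genes are untestable and logged. Weighted
deviations sum to zero within each gene by construction — uniform shifts
can never be called splicing, which is the mechanism behind the
expression/splicing orthogonality the pipeline reproduces on planted data.

Isoform scores are per-sample means of log2-CPM over user-designated
exon sets (`isoform_specific_expression()`), and
`correlated_gene_lists()` collects genes whose expression exceeds a Pearson
threshold (0.8 and 0.7 are the thresholds used in the headline analyses)
against each isoform score.

# VDJ scores

Burden is `1e6 × (VDJ reads) / library size`. The clonality of a clone
abundance vector is `1 − H/ln K` (H the Shannon entropy of clone
frequencies, K the clone count) — the complement of Pielou evenness. **The
source analyses never define their clonality formula**; this standard
repertoire metric is the package's choice, and single-clone samples score 1
by convention. Clonality is scale-invariant and decreases monotonically as
a dominant clone is redistributed (verified against direct entropy
computation).

# Histology prediction

Features per sample: the first three PCs of the gene signature (training
PCA, gene-centred, component signs fixed by positive loading sums), the
first three PCs of **relative exon usage** (exon log2-CPM minus the
per-gene mean, isolating splicing from expression), the median scores of
both signatures, VDJ burden and clonality. Validation cohorts are projected
with training loadings and never refit; leakage is asserted in tests by
shuffling validation rows and checking the report is unchanged.

`train_rf()` fits a 500-tree regression forest (ranger) with permutation
importance, drops features whose importance is non-positive in a majority
of 10 cross-validation folds, and refits on the retained set; everything is
deterministic given the seed. Validation reports Spearman rho and p (exact
for n ≤ 9, t approximation otherwise), Cohen's kappa on disease status
(default rule: score > 0, since synthetic controls score 0 up to clipped
noise — the source binarization is unstated), and the top-3 permutation
importances.

# Human translation

Ortholog projection supports `all` (expand one-to-many) and `one_to_one`
policies. Histology indices are regressed on the first five signature PCs,
each expanded in a restricted cubic spline basis with three knots at the
0.1/0.5/0.9 quantiles (k − 1 basis columns, linear tails, continuous second
derivatives — checked numerically). Model search is backward stepwise
deletion minimizing `AIC = n ln(RSS/n) + 2k`, deleting a PC's nonlinear
columns jointly and its linear column only after them ("extremizing" the
AIC is read as minimizing). Stepwise AIC retains any given pure-noise term
with probability near `exp(−1)`, so a few noise terms survive selection on
average — the tests assert the true driver is always kept and most noise is
pruned, not perfect exclusion, because perfect exclusion is not a property
AIC has.

The optimism correction refits the *entire selection* inside each of B =
300 bootstrap replicates: optimism is the mean of (R² of the bootstrap
model on its bootstrap sample − R² of that model on the original sample),
and the corrected value is apparent R² minus optimism. An intercept-only
model has R² defined as exactly 0 on any data, so its corrected value is
exactly 0. Corrected R² is far below apparent for deliberately overfit
pure-noise models (about n/2 candidate columns at n = 40) in every tested
seed.

Network overlap is an upper-tail hypergeometric test of two gene sets
within a stated universe (default: the network's node set, since the
headline universe is unstated); reported as −log10 p, the log base being
another unstated detail the package fixes explicitly. `first_neighbors()`
expands seeds by one undirected hop.

# The synthetic-data generator

`sim_config()` encodes the study conditions: 2 groups × 4 days × 10 mice,
NB counts with gamma-distributed dispersions (mean 0.1), log-normal library
sizes around 1e7 (gene) and 1e6 (exon). Planted structure:

* per-day fixed effects (log2 effect 2, half up / half down so the
  transcriptome stays compositionally balanced);
* persistent effects at every day — by default 3.27× the per-day count, so
  about 55% of the DE union is one-timepoint-specific, matching the
  observed fraction in DSS colitis;
* five trajectory classes shaped like the canonical templates (amplitude 2);
* isoform switches: a designated half of a gene's exons up-weighted by
  2^1.5 in disease, optionally time-profiled;
* exon bins partition a separate exon-scale NB total via Dirichlet-drawn
  baseline proportions, with **Dirichlet-multinomial inter-mouse usage
  scatter** (concentration 60, a few percent on the proportion scale, the
  reported magnitude of inter-individual splicing variability) — without
  it, planted switches are unrealistically noiseless disease markers;
* a latent per-mouse severity: a hit/rest day profile (6, 4, 8, 5) times a
  mean-one log-normal mouse factor (CV 0.25). Disease effect sizes are
  modulated by the mouse's severity relative to its day mean, so histology
  prediction has within-day signal; histology is `max(0, severity + N(0,
  0.5))`; VDJ clone tables draw total burden NB-increasing in severity and
  clone frequencies from a Dirichlet whose concentration decreases with
  severity.

A `structure_seed` (distinct from the sampling seed) fixes the gene-level
"genome" — baselines, dispersions, exon-bin structure, planted assignments
— so cohorts simulated with different sampling seeds share the severity →
signature link and cross-cohort transfer is meaningful.

One estimand subtlety: with severity modulation, the disease-vs-control NB
coefficient targets log2 of the *mean* fold change, which Jensen-inflates
the planted log2 effect (about 2.28 for a planted 2 at CV 0.25). Recovery
tests that check the estimate against the planted value therefore disable
modulation; recovery tests that check sensitivity and precision run under
the modulated default.

What the generator does **not** emulate: batch and technical covariates,
human cohort structure (age, sex, genetic PCs), sequence-level reads,
junction evidence, and correlated gene-gene co-expression beyond the shared
severity factor. Passing tests therefore demonstrate that the machinery
recovers the structure it models, not that real cohorts will behave as
cleanly.

# Problem sizes and determinism

The test suite and acceptance script use: 20 null replicates of 2,000 genes
(10 mice/group/day) for FDR calibration; 1,000-gene planted cohorts for
recovery and orthogonality; two 40-mouse cohorts (600 genes) for the
transfer experiment; 5,000 features for prior-df recovery; 20 seeds × 300
bootstrap replicates for the optimism check. These sizes keep a full run in
the minutes range on one CPU while leaving the measured properties stable
across seeds. Every stochastic stage takes an explicit integer seed, and an
end-to-end pipeline run is asserted to be bit-identical when repeated.

# Known limitations

* The NB dispersion is a plug-in (Pearson moments); at much smaller group
  sizes than the study design the LRT would need a finite-sample
  correction.
* Fuzzy c-means letters are defined only for day grids matching the
  canonical templates; other designs get unlabeled clusters.
* The stepwise-AIC selector inherits AIC's permissiveness toward weak
  terms; the bootstrap optimism correction, not the selector, is the
  overfitting guard.
* Random-effects structure (repeated measures within mouse) is out of
  scope; each sample is treated as independent, matching the
  cross-sectional sacrifice design.
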