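---
title: "Models and methods behind scDropletKit"
author: "scDropletKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scDropletKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models inside scDropletKit, the
choices made where the underlying procedures are genuinely open, and what
the synthetic-data generator does and does not emulate. It states no
empirical results beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The preprocessing model

**QC filters.** A barcode is kept when it has at least `min_genes = 500`
detected genes *and* a UMI total inside `[min_umi, max_umi] =
[4000, 13000]`. We read the two lower limits as a conjunction of two
minimums, and implement strictly-fewer / strictly-greater removal, so
cells sitting exactly on 500, 4,000 or 13,000 are kept. The UMI ceiling
is a crude doublet guard: a droplet holding two cells carries roughly
twice the RNA. Gene filtering (`min_cells = 3` expressing cells) runs
after cell filtering, so detection is judged on QC-passing cells; this
order is enforced and tested.

**Normalization.** `value(g,c) = log1p(count(g,c) · 10⁴ / N_c)` with
`N_c` the cell's UMI total. The invariant `Σ_g expm1(value) = 10⁴` holds
per cell to relative 10⁻⁶ and is asserted in the tests.

**Cell-cycle scores.** PCA is run on the per-gene centered (not scaled)
log-normalized expression of the annotated S and G2/M module genes, and
the two leading component scores are matched to phases by maximal
absolute Pearson correlation with each module's mean expression, then
sign-oriented to correlate positively. Centering without scaling keeps
highly expressed cycle genes influential, which is what makes the two
leading components cycle-dominated; the assignment-by-correlation step
removes the arbitrariness of component order and sign. If both
components best match the same module the structure is degenerate and the
function aborts with the correlation table. Below 5 genes per module we
refuse to score; below 20 we warn.

**Covariate regression.** For each gene, OLS of log-normalized expression
on intercept, both cycle scores, the per-cell UMI total, mitochondrial
fraction, run-indicator contrasts and alignment rate. Residuals are
z-scored per gene (zero-variance genes are carried as all-zero rows), and
no clipping is applied. Two readings fixed here: "number of UMIs" enters
as the per-cell total, since a per-gene quantity cannot enter a per-cell
design matrix; and "scaled Pearson residuals" of a Gaussian OLS model are
exactly the z-scored raw residuals, which is what we compute. Collinear
design columns (for example a run indicator in a single-run dataset) are
dropped with a warning, never silently — by QR rank detection, keeping
the pivoted leading columns.

## Dimensionality reduction and clustering

**Variable genes.** Per gene we compute `log1p(mean)` and
variance/mean of the *normalized* (expm1 of log-normalized) counts and
keep genes inside the bounds `[0.05, 8] × [0.5, 30]`, bounds inclusive.
Genes with zero mean have undefined dispersion and are excluded.

**PCA.** Singular value decomposition of the cells × variable-genes
residual matrix (rows already centered by construction). `k = 13`
components by default. SVD is deterministic up to component sign; the
sign is fixed by making the largest-magnitude entry of each loading
vector positive, so results are bit-reproducible. Requesting more
components than the numerical rank is an error reporting the attained
rank.

**Neighbor graph.** Each cell is joined to its `n_neighbors = 30`
Euclidean nearest neighbors in PC space; each edge is weighted by the
Jaccard overlap of the two endpoint neighbor sets (each including the
cell itself). The source procedure specifies only "a cell–cell distance
matrix"; k = 30 with shared-neighbor weighting is the standard choice for
modularity clustering at these cell counts and makes the graph sparse and
noise-robust. Distances are computed exactly (no approximate NN), which
is fine at the 10³–10⁴-cell scale this package targets.

**Louvain.** igraph's Louvain implementation at resolution 1, with the
RNG seeded; labels are relabeled contiguously from 1 in order of first
appearance.

**Random-forest merge validation.** The merge step asks, for every pair
of clusters, whether a classifier can actually tell them apart. Design
choices where the procedure is underdetermined:

* *Features*: log-normalized expression of the variable genes — not
  residuals — because the classifier should see what a biologist calls
  "expression level".
* *Class balance*: the larger cluster is downsampled to the smaller's
  size before training. Without this, OOB error is dominated by the
  majority class and a fixed 11% threshold changes meaning with cluster
  size ratio.
* *Forest*: ranger with 500 trees, √p features per split, no depth
  limit, one thread (determinism), a per-evaluation seed derived from the
  stage seed.
* *Iteration order*: all current pairs are evaluated; if any exceeds the
  11% OOB threshold, the single worst pair is merged, cached errors
  touching the merged clusters are invalidated, and the scan repeats.
  Merging the worst pair first makes the procedure deterministic and
  order-independent.
* *Boundary semantics*: a pair merges only when its error strictly
  exceeds the threshold. Hence a threshold of 1 can never merge anything,
  and a threshold of 0 collapses any pair with positive error — the two
  ends of the dial are "trust the partition" and "trust nothing".
* Clusters below 10 cells are skipped with a warning: OOB error on a
  handful of cells is noise.
* The final judgment-call merge of clusters differing only in technical
  metrics is supported as an explicit `manual_merges` configuration
  directive, never applied automatically.

`merge_history` records every evaluation (pair, OOB error, action), and
replaying it reconstructs the final labeling from the initial one — a
property the tests assert.

**Sub-clustering** reruns variable-gene selection, PCA, graph building,
Louvain and the merge step on the chosen cells only, with labels
namespaced `"<parent>.<sub>"` so they cannot collide across parents.
**t-SNE** (Rtsne, Barnes–Hut, seeded, perplexity capped at (n−1)/3 for
small subsets) provides visualization coordinates that carry no
downstream semantics.

## Markers and summaries

The one-vs-rest Wilcoxon rank-sum test uses the normal approximation with
the standard tie correction and no continuity correction; the unit tests
pin it against `stats::wilcox.test`. Genes are tested when detected in at
least `min_pct = 0.1` of cells on either side, and the Bonferroni
universe is the number of genes actually tested, with both facts recorded
in the result's metadata. The reported `avg_log_fc` is the difference of
mean log1p-normalized expression (cluster − rest); this definition is
stated in the output metadata since the field uses several.

The kappa/lambda ratio calls each plasma cell by the larger summed
log-normalized expression over the kappa and lambda gene sets (defaults
IGKC vs IGLC1/2/3/7, configurable), leaves exact ties — including
all-zero cells — unassigned, and refuses clusters under 25 cells, where
the ratio is unstable. Note that summing *log* expression over sets of
different sizes favors the larger set when off-chain background
expression is non-negligible; with realistic light-chain restriction
(plasma cells transcribe essentially one chain class) the rule is
unambiguous.

## Droplet QC models

**Occupancy.** Under Poisson loading the MLE of the mean occupancy is the
histogram mean. The chi-square GOF test pools bins from the upper tail
until every expected count is ≥ 5, extends bins beyond the observed
maximum while the fitted model still expects appreciable mass there
(zero observed droplets at an occupancy the model predicts is evidence
against the fit), and spends one degree of freedom on the estimated mean.
Fewer than two free bins, or all mass at zero, is flagged degenerate
rather than tested.

**Collisions.** λ = concentration × droplet volume (cells/µL × nL ×
10⁻³); multiplet fraction among occupied droplets
`1 − λe^{−λ}/(1 − e^{−λ})`. The barnyard caller labels a barcode mixed
when neither species reaches a purity of 0.9 (a choice we expose and
report, since the underlying procedure never defines its doublet rule),
and converts the observed cross-species fraction to a total collision
rate by dividing by 2pq — the probability that a two-cell collision is
visible across species at human fraction p.

**ERCC metrics.** Sensitivity is the per-barcode total of detected
molecules after discarding barcodes under 100 UMIs; accuracy is the
per-barcode Pearson correlation between `log1p(detected)` and
`log(expected molecules)` over *all* reference species, zeros included —
`log1p` on the detected side admits the zeros that dominate diluted
references. Expected molecules per droplet are concentration ×
602,214.076 molecules per attomole × volume (µL) / dilution.

## The synthetic-data generator

Counts for cell c, gene g are Poisson with mean
`s_c · θ_g · F(g, cluster(c)) · B(g, run(c)) · C(g, c)`, renormalized per
cell so the realized library size tracks `s_c`: log-normal library sizes
(median 8,000, sdlog 0.15 — inside the QC window), log-normal baseline
abundances, cluster markers at natural-log fold change 2, run batch
factors on a random gene subset, and a cell-cycle factor
`exp(effect · phase score)` on the module genes. Phase scores come from a
three-state mixture (G1 near zero; S-high; G2M-high) so the regression
stage faces a realistic confounder. Mitochondrial pseudo-genes (`MT-`
prefix, matching standard human annotation) absorb a Beta(20, 380)
per-cell fraction of the budget. Poisson (not negative-binomial) noise is
the default because UMI-level noise in droplet data is near-Poisson; a
Gamma `overdispersion` knob exists for sensitivity analyses.

Three calibration choices in the cycle module, fixed at design time:
module sizes 43 (S) and 54 (G2/M), the sizes of the standard annotated
cycle lists; a +1 log baseline-abundance boost for module genes, since
cycle machinery is well expressed (this puts roughly a tenth of the
library on the modules); and a G2/M phase amplitude of 1.4 versus 1.0
for S, reflecting that mitotic signatures swing harder. The amplitude
asymmetry also matters statistically: with exactly equal module
variances the two leading principal components of the cycle genes are an
arbitrary 45° rotation of the phase plane, and phase assignment is
ill-posed for any method.

For the barnyard generator a barcode exists only where a bead and at
least one cell co-occur, so occupancy is zero-truncated Poisson; empty
droplets are counted only by `simulateEncapsulation`. The
droplet-to-barcode conversion efficiency is not fixed by the underlying
procedure, so the generator simply emits a requested number of occupied
barcodes. ERCC counts are binomial thinnings of the rounded expected
molecule counts.

What the generator does **not** emulate: gene-length and sequence biases,
ambient RNA, PCR chimeras, read-level structure (no FASTQ), patient-level
biological variance beyond run batch factors, and doublets in the
clustered generator (doublets live in the barnyard model). Passing tests
therefore demonstrate algorithmic correctness under a controlled
generative model, not robustness to every artifact of real tissue data.

## Problem sizes and seeds

The test suite runs the full pipeline at 8 clusters × 150 cells × ~2,000
genes (the generator's default study design), the regression-recovery
suite at 2,000 cells, merge-decision replication over 20 seeds, occupancy
calibration over 200 simulations of 10⁵ droplets, and barnyard/ERCC
checks at a few thousand barcodes — sizes chosen so each property is
measured well inside Monte-Carlo error while the whole suite stays quick
on a laptop. Every stochastic step takes an explicit seed, RNG state is
restored after each call, and two runs with identical configuration are
byte-identical — also asserted in the tests.

One statistical note on the regression-recovery check: with ~100 affected
genes at n = 2,000 cells, the maximum over genes of a *null* correlation
is ≈ 0.07 by sampling noise alone, so the package asserts the mean
absolute residual correlation (< 0.05) rather than a per-gene maximum; a
per-gene bound at that level is unattainable by any estimator that does
not already know the planted scores.

## Known limitations

* OLS residual correction assumes approximately Gaussian noise on the
  log scale; for very low counts Pearson-residual GLM approaches differ.
* The merge procedure's 11% OOB threshold is a calibrated constant, not
  an adaptive test; its meaning depends on the balanced-downsampling
  choice documented above.
* Exact kNN costs O(n²) memory in the graph step; beyond ~2 × 10⁴ cells
  an approximate-NN backend would be needed.
* t-SNE coordinates are for visualization only and are not stable across
  perplexities; no quantitative claim should be read off them.
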