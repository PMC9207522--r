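---
title: "Methods: stage-resolved oocyte transcriptome analysis"
author: "oostage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved oocyte transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oostage)
```

# Scope and model

`oostage` implements a staged bulk RNA-seq analysis as used for zebrafish
oocyte development, where oocytes are size-separated into five
developmental groups — Symbrk (symmetry breaking), Nuc (nuclear cleft),
MatBb (mature Balbiani body), StageII (cortical alveolus) and StageIII
(vitellogenesis) — and each group is sequenced in biological duplicate.
The statistical model throughout is the negative binomial (NB) for raw
counts,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij},\ \alpha_i), \qquad
  \mu_{ij} = s_j\, q_{i,\rho(j)}, \qquad
  \mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with per-sample size factors $s_j$, per-gene dispersion $\alpha_i$, and a
log-link GLM in the stage factor $\rho(j)$. Two tests are run per gene: a
likelihood-ratio test (LRT) of the stage-factor model against the
intercept-only model (chi-square, $\mathrm{df} = \#\mathrm{stages} - 1$),
and pairwise Wald tests between stage pairs (coefficient over its
standard error, two-sided normal). p-values are Benjamini–Hochberg
adjusted per test family, with no independent filtering.

## Preprocessing

* **Low-count filter.** Genes with a raw-count row sum below 6 over all
  samples are removed before normalization (`filterLowCountGenes()`,
  strict: a sum of exactly 6 is retained).
* **Normalization.** Median-of-ratios size factors
  (`estimateSizeFactors()`): per sample, the median over reference genes
  of $K_{ij} / (\prod_j K_{ij})^{1/n}$, the reference set being the genes
  with no zero count. The median is taken on the log-ratio scale so an
  even-sized reference set interpolates geometrically, matching the
  standard reference implementation exactly.
* **baseMean** is the mean of size-factor-normalized counts over *all*
  samples, so it is identical across contrasts.

## Dispersion estimation

The gene-wise estimator is method-of-moments on normalized counts,
pooled over stages with at least two replicates:
$\hat\alpha_i = \max(\text{floor},\ \sum_s (n_s-1)\,
(\hat v_{is}-\hat m_{is})/\hat m_{is}^2 \,/\, \sum_s (n_s-1))$ with floor
$10^{-8}$ (the Poisson limit). At duplicate-level replication this
plug-in has only 5 residual degrees of freedom and is far too noisy for
calibrated tests: in a null simulation (5,000 flat genes,
$\alpha = 0.1$), plugging it straight into the LRT inflated the
p < 0.05 rate to 0.18. The default estimator therefore fits a parametric
mean trend $\alpha(\mu) = a_0 + a_1/\mu$ to the gene-wise values by least
squares and assigns each gene the trend value at its baseMean
(`estimateDispersions(method = "trend")`), which restores calibration
(0.055 in the same simulation; the oracle using the true $\alpha$ gives
0.050). This borrows strength across genes the way empirical-Bayes
shrinkage does, without reproducing any particular shrinkage recipe;
`method = "genewise"` remains available and is the better choice when
replication is deep (its median is within 25% of truth at 10 replicates).
The trend fit needs at least 50 genes whose gene-wise estimate is above
$10^{-6}$; below that the function falls back to gene-wise values with a
message.

## GLM fitting and edge cases

Per-gene fits use iteratively reweighted least squares with fixed
$\alpha$, working weights $w = \mu/(1+\alpha\mu)$, convergence when the
largest coefficient change drops below $10^{-8}$, and a 100-iteration
cap. Fitted means are clamped to $[10^{-8}, 10^{12}]$ and coefficients to
$\pm 50$ (natural log), so fully separated genes — a stage group of all
zeros — converge to the boundary instead of diverging; such a fit whose
final step has stalled below 0.1 at the mean floor is treated as
converged at the boundary. Reported log2 fold changes beyond $\pm 30$
are capped there and flagged `lfc_capped`. No pseudocounts are added and
no fold-change shrinkage is applied: the reported effect is the
unshrunken MLE. Non-converged genes are flagged, get NA p-values, and are
excluded from the BH denominator. BH is applied per contrast (each
pairwise family separately), the usual behaviour of per-contrast result
tables.

# DEG calling

Two filters are exposed because both appear in this style of analysis:

* `callDEGs()` — membership iff baseMean > 5 (strict), padj < 0.05
  (strict), and $|\mathrm{log2FC}| > 5/\sqrt{\mathrm{baseMean}} + 0.6$
  (strict). The threshold demands a stronger fold from lowly expressed
  genes and tends to 0.6 for highly expressed ones. For LRT tables,
  which carry no single fold change, the criterion is evaluated on the
  largest-magnitude pairwise log2 fold change per gene when supplied
  (the pipeline supplies it), and otherwise skipped with a recorded
  flag — whether the fold criterion applied to the across-stage list,
  the pairwise lists, or both is genuinely ambiguous, so both paths are
  explicit and labelled.
* `callDEGsSimple()` — fold change at least 2 (inclusive) and
  FDR < 0.05 (strict), the rule used for pairwise Venn partitions
  (`vennPartition()`).

The padj threshold is 0.05 by default with 0.1 available through
`padjCut`: source analyses used both in different places, and the choice
is surfaced rather than hidden.

# Trend clustering

The LRT-significant genes are summarized as replicate-averaged stage
means of normalized counts (`stageMeanMatrix()`), then row z-scored to
mean 0, population SD 1 (`rowZScore()`); constant rows are dropped with
a message. Averaging precedes z-scoring — the order is not dictated by
anything upstream, and averaging first matches the convention of
plotting the mean profile per stage; this is recorded as an assumption.
Z-scoring of raw-scale stage means is the standard symmetric heatmap
scaling; note that for single- and pair-stage archetypes the z-scored
shape is exactly invariant to the fold magnitude.

Clustering is Euclidean k-means: 25 restarts of Lloyd's algorithm from
k-means++ seedings, keeping the lowest-inertia solution, cluster ids
relabelled by descending size, all deterministic given the seed
(default 42). k is a user parameter with defaults 12 (fine) and 5
(representative); no selection rule is imposed because none is implied
by the analysis being reproduced. `matchTrendTemplates()` labels
centroids by maximal Pearson correlation with the five canonical
templates (early-only, early-pair, increasing, mid-peak, late-pair);
ties break by template priority order with a warning, and degenerate
centroids are labelled "custom".

# Ortholog collapse and coverage

The zebrafish-to-human conversion distinguishes 1:1 orthology
(pass-through) from one-to-many orthology, where several zebrafish
paralogs share one human gene (a legacy of the teleost genome
duplication). `directionalityCollapse()` applies the directionality
test per human gene over the zebrafish genes *present in the DEG set*:
all same direction → included with that direction; any opposite
significant change → omitted with a conflict record; paralogs that are
not significant do not veto (the rule quantifies over DEGs only).
Unannotated DEGs become unresolved records, and every DEG lands in
exactly one of contributor / conflict / unresolved. Groups larger than
two use the same all-same-sign rule. Each pairwise contrast is collapsed
independently, and the significance of paralogs is judged within the
same contrast. Genes with only "associated" (uncurated) human orthologs
are treated as unannotated.

`orthologCoverage()` implements the coverage arithmetic: with
one-to-one fraction $f_{11}$, one-to-many fraction $f_{1m}$ (percent of
annotated genes) and concordance $c$ among one-to-many cases, effective
coverage is $f_{11} + c \cdot f_{1m}$ and the residual requires manual
curation. The published curated counts (9,722 / 5,361 / 15,122) do not
sum exactly — 39 annotated genes are unclassified — so the function
takes the counts and the annotated denominator as given rather than
forcing them to close; on tables generated by this package every
annotated gene is classified and the two fractions sum to 100%.

# Enrichment

`hypergeometricORA()` is a generic over-representation analysis standing
in for proprietary pathway tools: one-sided upper-tail hypergeometric
p-values ($P[X \ge k]$), terms intersected with the background before
testing, BH across tested terms, FDR < 0.05 flag. The default
background in the pipeline is the human universe produced by the
orthology table — the least-biased choice when no background is stated.
Only enrichment is tested, not depletion.

# Synthetic data: what it does and does not emulate

`simConfig()` / `simulateDataset()` generate NB counts with the
structure the analysis assumes:

* five stages in duplicate (both configurable);
* per-gene baselines log-uniform in a configurable range (default
  5–500 counts), dispersions log-normal (default median 0.05, typical
  of bulk RNA-seq), size factors log-uniform in [0.7, 1.4] applied
  multiplicatively;
* planted trend archetypes mirroring the five canonical shapes, with
  stage multipliers 1 (low) and the effect fold (high; geometric ramp
  for "increasing"), fold drawn log-uniformly from a configurable range;
* a paralog-bearing orthology table in which a configurable fraction of
  human genes receive two zebrafish paralogs and, among pairs whose both
  members carry a planted direction, the directions agree with
  probability `concordance` (default 0.8, the published concordance);
  a configurable fraction of genes is left unannotated.

One master seed drives named sub-seeds so each generator is
independently reproducible. The simulator does **not** model GC or
length bias, read-level noise, somatic-cell contamination (handled in
the source analysis by excluding a stage, not by modelling), outlier
samples, or correlated gene-gene structure; passing recovery tests on
this generator therefore demonstrates correctness of the statistical
machinery under the assumed model, not robustness to the full
complexity of real libraries. The mid-peak archetype has unchanged end
stages, so its planted end-to-end direction is 0 and it does not
participate in concordance bookkeeping.

# Verification problem sizes

The checks shipped with the package use deliberately moderate sizes
chosen to exercise the asymptotics that matter while keeping the suite
quick to run: type-I calibration on 5,000 flat genes (5 × 2 design,
$\alpha = 0.1$); recovery of planted 8-fold DEGs among 2,000 genes
(60% null, $\mu \in [50, 500]$, $\alpha = 0.02$) — conditions under
which the pipeline attains sensitivity ≈ 1 at near-zero observed FDR;
trend recovery on 1,500 genes across five equally likely archetypes at
fold 8 and $\alpha = 0.01$, where k-means recovery is exact (adjusted
Rand index 1); and 1,000 random small orthology tables checked exactly
against brute-force sign enumeration.

# Known limitations

* The dispersion trend is a two-parameter parametric form; data with a
  non-monotone mean-dispersion relationship would be better served by
  the gene-wise estimator plus deeper replication.
* With duplicates, the LRT retains mild small-sample liberality (about
  0.05–0.07 at nominal 0.05); this is documented rather than corrected.
* No outlier handling (no Cook's-distance replacement) and no
  multi-factor designs.
* The fold-change cap at ±30 makes fully separated genes reportable but
  their magnitudes are a floor artifact, not estimates.
* `vennPartition()` reports counts per membership signature; it does not
  draw the diagram.
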