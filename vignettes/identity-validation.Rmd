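---
title: "Validating induced-microglia transcriptome identity with microgliaID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating induced-microglia transcriptome identity with microgliaID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgliaID)
```

## The scientific question

Monocyte-derived induced microglia-like cells (iMG) are an accessible
cellular model for brain-resident microglia. The claim that matters is a
transcriptome-level one: after induction with IL-34 and GM-CSF, do iMG
cells move away from monocytes and induced macrophages (iMacs) and toward
primary human microglia? Answering it requires comparing a small in-house
RNA-seq study against published microglia references, which brings three
obstacles: different studies have different library sizes and batch
structure, the comparison must be anchored on genes that actually carry
microglial identity, and agreement between datasets has to be quantified,
not eyeballed.

`microgliaID` implements that validation as a reusable, fully testable
pipeline over gene-by-sample count matrices: normalization, embedding,
clustering, a cross-dataset fold-change consistency score with a
signature-gene filtering cascade, presence-based Venn partitioning of
expressed genes, negative-binomial differential expression, and the
2^-ddCT qPCR readout used for polarization experiments. A synthetic-data
module generates count matrices with known planted structure so every
stage can be exercised and checked against truth without any external
download.

## The consistency score and the signature cascade

The centrepiece statistic compares, gene by gene, the fold change from
monocytes to microglia-like cells in the dataset under validation
(\(x\)) with the fold change from monocytes to microglia in a reference
dataset (\(y\)):

\[ s(x, y) = \frac{2xy}{\sqrt{x^2 + y^2}} . \]

Two properties make it useful. Same-sign fold changes score positively
and opposite-sign fold changes negatively, regardless of magnitude; and
along the diagonal \(s(x,x) = \sqrt{2}\,x\), so the score grows with
effect size. With the conventional cutoff of 0.50 (strict), no gene whose
fold changes are both below \(0.50/\sqrt{2} \approx 0.354\) can be called
consistent, which protects the call set from noise-level agreement. The
score is 0 at the origin by convention, symmetric, and positively
homogeneous (\(s(cx,cy) = c\,s(x,y)\) for \(c>0\)).

We compute \(x\) and \(y\) as **signed log2 fold changes** of
size-factor-normalized group means (pseudocount 1). The score's
sign-sensitivity and a cutoff of 0.50 are only meaningful on a scale
symmetric about zero; linear ratios (which are bounded below by 0 and
centred on 1) would make discordance invisible. Because the published
description says only "fold change", the linear alternative remains
available via `fc_scale = "linear"` for sensitivity analysis, and the
choice used is recorded in the `CascadeResult`.

The cascade filters a curated signature list in four stages:

1. `signature_union` — the union of published microglial signature lists
   (deduplicated case-insensitively, the same normalization used for
   cross-dataset gene matching);
2. `overlap_with_data` — signature genes present in both datasets;
3. `consistent` — genes with \(s(x,y) > 0.50\);
4. `de_filtered` — consistent genes that also pass the test-side
   differential-expression filter \(|FC| \ge 1.2\), \(p \le 0.001\) and
   mean normalized count \(\ge 5\).

Boundary conventions follow the wording of the criteria they implement:
the consistency and presence cutoffs are strict (`>`), the stage-4 DE
thresholds are inclusive (`>=`, `<=`), and the volcano classification
(`adj_p < 1e-16`, `|log2FC| > 2`) is strict on both axes. The stage-4
p-value is the raw Wald p by default — the FDR-adjusted value is used
only where an FDR is explicitly part of the threshold (the volcano plot) —
with `use_adjusted_p = TRUE` available for the stricter reading.

## Normalization chain

*Size factors* are median-of-ratios: per sample, the median over genes
with no zero count of the ratio to the gene's geometric mean. "Library
size" normalization is deliberately this estimator rather than
counts-per-million because the downstream presence threshold
("normalized counts > 10") and expression floor ("average expression
>= 5") are calibrated to that scale, and because it is robust to a
minority of strongly differential genes. One knock-on effect is worth
knowing: with a one-sided planted signature carrying several percent of
the library, any ratio-based normalizer absorbs a small compositional
shift (of order 0.1 log2 units at 7.5% signature mass), common to all
genes; contrasts between gene groups are unaffected.

*FPKM* is \(10^9 k_{gs} / (L_g N_s)\) with \(L_g\) the transcript length
and \(N_s\) the column total, giving the exact identity
\(\sum_g \mathrm{FPKM}_{gs} L_g = 10^9\) used as a test oracle.

*The variance-stabilizing transform* uses the closed form for the NB
variance function \(v(\mu)=\mu+\alpha\mu^2\) with one pooled dispersion:

\[ \mathrm{vst}(x) = \tfrac{2}{\ln 2}\,\mathrm{asinh}\sqrt{\alpha x}
   \;-\; \log_2(4\alpha), \]

affinely calibrated so \(\mathrm{vst}(x) \to \log_2 x\) for large
counts. Full DE toolchains fit a per-gene dispersion trend before their
VST; we intentionally do not, because clustering and embedding need only
monotonicity and variance flattening, both of which the pooled form
provides, and a single `dispersion` argument keeps the transform
transparent and exactly reproducible. The default of 0.1 corresponds to a
between-donor coefficient of variation around 30%, typical of bulk RNA-seq
on primary human cells.

*Batch removal* fits, per gene, expression on condition plus batch
(delegated to the standard linear-model implementation,
`limma::removeBatchEffect`) and subtracts the batch coefficients, with a
recentering step so each gene's grand mean is preserved exactly even for
unbalanced batches. Protecting cell type is the right model when
conditions are replicated across batches — but in the cross-dataset
design each cell type lives in exactly one study, so condition and batch
are aliased and the protected fit is not estimable. `runPipeline()`
detects this nesting and runs the batch fit unprotected, which equalizes
per-gene study means while preserving within-study contrasts; the
within-study geometry is what the embedding and clustering read.
`correctBatchEffect()` errors loudly on a confounded protected design
rather than silently dropping coefficients.

*Rescaling* maps each gene to [0, 1] (min-max); a constant gene maps to
0 by convention — the only ambiguous case, so it is pinned by a test.

## Embedding and clustering

PCA is the SVD of the gene-centred matrix; classical (Torgerson) MDS
double-centres the squared distance matrix and scales eigenvectors by
root eigenvalues, reporting (but never using) negative eigenvalues.
Euclidean distance on the normalized matrix is the default metric, with
correlation distance available. Axis signs are fixed by forcing the
largest-magnitude coordinate positive, so output is identical across
linear-algebra backends. On Euclidean distances the two embeddings agree
up to an orthogonal transform, which the test suite checks to 1e-8 by
Procrustes; agreement of two algorithmically different routes is the
strongest cheap correctness check available for both.

Hierarchical clustering (complete/average/single linkage) returns the
standard merge history. Two quantitative summaries replace visual
inspection of heatmaps: `clusterPurity()` (cut into \(k\) clusters, count
majority-class members) and `nearestReferenceCentroid()` (which reference
population's centroid each iMG sample lands nearest in MDS space). These
make "iMG clusters with reference microglia" a machine-checkable claim.

## Differential expression

The test is a two-group NB Wald test with per-gene dispersion estimated
by method of moments from within-group means/variances of normalized
counts (floored at 1e-8), then shrunk 50/50 toward the mean raw estimate
in the gene's expression decile. The shrinkage is a deliberately simple
trend blend: full empirical-Bayes curve fitting buys little for a
validation pipeline and would obscure what the estimator does.

The group mean \(\hat q\) is the mean of size-factor-normalized counts
and the Wald SE comes from the NB Fisher information,
\(\mathrm{Var}(\ln\hat q) = (1+\alpha q)/(nq)\) per group. We compute all
statistics from normalized counts rather than threading per-sample
offsets through the likelihood: the two coincide when size factors are
equal, and the normalized-count form makes the pipeline *exactly*
invariant to rescaling a sample's counts together with its size factor —
a property we consider part of the method's contract and verify to 1e-9.
A group with all-zero counts is floored at half a normalized count so
fold changes stay finite; genes with zero counts everywhere are dropped
and reported separately. No fold-change shrinkage is applied, since the
thresholds downstream are on raw fold changes.

Calibration is checked by simulation at the suite's standard conditions
(2000 genes, dispersion 0.1, 10 vs 10): observed type-I error at nominal
0.05 must fall in [0.03, 0.07], and planted 8-fold changes on 50 genes
must be detected at BH-adjusted p < 0.05 for at least 90% of genes.

## The synthetic-data generator

`simulateCounts()` draws NB counts (variance \(\mu + \alpha\mu^2\), the
same parameterization the DE module assumes) for five populations —
monocyte, iMac, iMG, reference microglia, reference monocyte — across two
studies. Defaults are the study design the pipeline targets: 3 monocyte,
3 iMac and 4 iMG libraries in the test study, 4 reference microglia and 3
reference monocytes in the reference study; library sizes uniform on
[0.8, 1.2] million (desk scale — large enough for the presence and
expression thresholds to behave as they do at sequencing depth, small
enough that the whole suite runs in seconds); baseline means log-normal
around 100; dispersion 0.1.

Planted structure: a signature gene set (default 150 of 2000 genes)
carries `signature_log2fc` (default 2) in iMG *and* reference microglia
relative to monocytes, and half that effect in iMacs — macrophages
share part of the microglial program, which is exactly what makes the
iMac contrast informative. Each population additionally receives its own
marker program (5% of genes, log2 effects with SD 1.5). Without markers,
the two monocyte populations would be statistically identical and no
clustering method could separate them; with markers, all five populations
are distinguishable while the iMG–reference-microglia affinity still runs
through the shared signature. Batch effects are per-gene per-study
log-normal multiplicative shifts (log2 SD 0.25), matching the
additive-in-log model the batch correction assumes. Per-sample gene
weights are renormalized so each column's expected sum equals its drawn
library size. All draws flow from one seeded stream; the caller's RNG
state is untouched.

`simulatePairedSignature()` generates the matched test/reference pair
used to validate the cascade: of a 200-gene signature, 80 genes change
concordantly in both datasets, 40 discordantly, 80 not at all.

What the generator does not emulate — and therefore what passing tests do
not establish about real data: GC/length bias, unmodelled covariates
beyond a single batch factor, count outliers, gene–gene correlation
within programs, and annotation mismatch between studies beyond symbol
casing. Results on real cross-study data still depend on those factors.

## qPCR readout

`ddctFoldChange()` implements Livak relative quantification with the mean
control \(\Delta CT\) as baseline, retaining per-replicate folds for the
mean ± SD report; `groupCompare()` routes two groups to Student's t-test
and more to one-way ANOVA. Exact arithmetic identities (equal
\(\Delta CT\) gives fold 1; a 2-cycle drop gives fold 4; additive CT
offsets cancel) are pinned in tests.

## Problem sizes and determinism

The test and acceptance workloads run at 600–2000 genes and 17–80
samples, sizes chosen so the full suite completes in well under a minute
while keeping every statistical check (type-I error over 2000 genes,
cascade recovery of 120 planted genes, cluster purity over 17 samples)
adequately powered. `runPipeline()` writes a `summary.json` that is
byte-identical across reruns with the same configuration and seed; the
cluster-purity criterion is intrinsically stochastic at 17 samples (a
single merged monocyte pair costs 2/17), which is why it is evaluated
under a fixed seed.

## Known limitations

- The VST uses one pooled dispersion, not a fitted trend; very
  low-count genes are stabilized less accurately than a full DE
  toolchain would manage.
- The dispersion estimator's decile-trend shrinkage is coarser than
  empirical-Bayes alternatives; at 3–5 samples per group its Wald test
  should be read as indicative, which is why the cascade's expression
  floor and fold-change threshold do most of the filtering work there.
- Cross-dataset gene matching is by case-insensitive symbol only; no
  identifier mapping or alias resolution is attempted, and symbols that
  differ between annotations simply drop out at the overlap stage.
- Unprotected batch removal in the fully nested design removes any true
  global expression difference between studies along with the batch
  effect; that is inherent to the design, not to the implementation.
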