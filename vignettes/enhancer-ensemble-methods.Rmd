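---
title: "Two-layer ensemble enhancer prediction: models, parameters and design notes"
author: "enhancerEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer ensemble enhancer prediction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Enhancers are distal cis-regulatory elements. Genome-wide they are hugely
outnumbered by non-regulatory sequence, so a supervised predictor faces a
severe class imbalance (this package works at the conventional 1:10
positive:negative training ratio, and the genome-wide reality is far worse).
A single classifier trained on such data drifts toward the majority class.

The framework implemented here attacks the imbalance with a two-layer
committee architecture:

1. **First layer — partitioned SVM committees.** The training data of each
   dataset (cell line or tissue) is split into disjoint learning subsets
   and one Gaussian-kernel (RBF) SVM is fitted per subset. Two partition
   modes exist:
   * *both-classes* (`partitionDataset(mode = "both-classes")`): positives
     and negatives are independently shuffled and split into `nParts`
     subsets, each holding the two classes at the original 1:10 ratio.
     This is the mode for very large histone-mark datasets (published
     configuration: 4 cell lines x 1000 subsets = 4000 members).
   * *majority-only* (`mode = "majority-only"`): only the negatives are
     split; every subset holds all positives and a 1/`nParts` slice of the
     negatives, so each member sees a locally balanced problem (published
     configuration for the sequence flavors: 10 subsets).
   For a query sample every member casts a hard vote and the committee
   reports the fraction of positive votes (`ensembleConfidence`), a score
   on the lattice 0, 1/M, ..., 1.
2. **Second layer — score aggregation.** The per-dataset confidence scores
   (4 for the histone flavor, 5 for the tissue-sequence flavor, or the 10
   individual member votes when there is a single committee) feed a small
   feed-forward neural network with one hidden layer of logistic units and
   a sigmoid output (`tuneAnn`), cross-validated over candidate hidden
   sizes. A per-column majority vote (`majorityVote`) is available as the
   simple alternative.

## Feature spaces

* **hist11** — per 200-bp bin, the mean signal of 11 histone-modification
  ChIP-Seq tracks (H2AFZ, H3K27ac, H3K27me3, H3K36me3, H3K4me1, H3K4me2,
  H3K4me3, H3K79me2, H3K9ac, H3K9me3, H4K20me1), each attribute min-max
  scaled to [0,1] *within one dataset* (`minmaxNormalize`). Scaling is
  never pooled across datasets, so a model trained on one cell line can
  be applied to another that was scaled independently.
* **seq351** — 351 attributes computed from the region sequence alone:
  the 4 + 16 + 64 + 256 mono- to tetranucleotide frequencies
  (lexicographic order, forward strand, windows containing non-ACGT
  characters excluded from numerator and denominator), a CpG-island flag,
  the C+G and A+T aggregate frequencies, the sequence length and the
  count of unambiguous bases, and six derived composition attributes:
  CpG observed/expected ratio, GC skew (G-C)/(G+C), AT skew (A-T)/(A+T),
  purine fraction, keto fraction, and the (C+G)-(A+T) frequency
  difference. No dataset-level scaling is applied to this schema.

The exact identity of the island flag and the six derived attributes was
not fixed by the published main text; the choices above are standard
composition statistics, isolated behind `seqFeatureSchema()` so they can
be swapped without touching any other module. The CpG-island flag uses the
classical criterion: length >= 200 bp, GC >= 0.5, observed/expected CpG
>= 0.6 (with obs/exp computed on unambiguous bases and defined as 0 when
no C or no G is present).

# Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `binWidth` | 200 | bp | featurization and scanning unit; trailing partial bins are dropped so every bin is exactly `binWidth` bp |
| negative:positive `ratio` | 10 | — | applied when sampling negative bins or length-matched negative regions |
| `nParts` | 1000 / 10 / 10 | — | committee size per flavor (encode / fantom5 / vista); scaled-down runs override it |
| `trainFraction` | 0.20 / 0.40 / 0.20 | — | stratified train share per flavor |
| `tuneFraction` | 0.70 | — | share of a learning subset fitted during hyperparameter search; GM scored on the rest |
| `GridSpec` C bounds | [1, 500] | — | SVM regularization search box |
| `GridSpec` gamma bounds | [1e-5, 5e4] | — | RBF width search box; the published box has no lower bound, 1e-5 makes the log lattice finite |
| `log10Step` | 0.2 | log10 | round-1 lattice step; round 2 refines ten-fold (step 0.02) in a +/- 0.2 window around the optimum, clipped to bounds |
| `hiddenCandidates` | 1..10 | units | ANN hidden sizes tried by 5-fold stratified CV |
| aggregator `threshold` | 0.5 | — | decision cut on the output probability; majority vote uses a strict majority with exact ties negative |

The model-selection criterion everywhere is the geometric mean
GM = sqrt(sensitivity x specificity), which collapses to 0 whenever a
classifier abandons one class — the property that makes it the right
score under imbalance. Grid-search ties break toward smaller C, then
smaller gamma (a preference for the smoother model that also makes the
search deterministic).

## SVM input scaling

Member SVMs are fitted with libsvm's internal per-attribute
standardization (the e1071 default) left on. This is part of the
classifier, not a dataset normalization step: the seq351 schema mixes
frequencies of order 0.01 with raw lengths of order 1000, and without
input standardization the RBF distance is dominated by the length
attributes — which carry no class signal once negatives are
length-matched — leaving the composition signal invisible at any single
gamma. The "no normalization" contract of the sequence flavor refers to
the feature vectors themselves, which are indeed exported and consumed
raw.

# The synthetic testbed

The package must be testable end to end without any external download, so
`synthSpec()` / `makeMultiDatasets()` generate the data regimes the
framework assumes:

* a genome of i.i.d. bases at background GC 0.41 (the human genome-wide
  value), default 2 x 120 kb;
* planted enhancers (default 15 per dataset, 600-1000 bp) rewritten at
  GC 0.56 with a CGCG 4-mer inserted at 5-fold its background rate —
  the GC shift of +0.15 and the 5x motif enrichment define the package's
  "separable setting";
* decoy promoters at GC 0.50, at least 1 kb away from every other planted
  region, so that promoter-like signal is present as a confounder;
* per-mark signal tracks: truncated-Gaussian noise (sd 1) plus the mark's
  amplitude inside enhancers (H3K4me1, H3K27ac high: 4 units) and inside
  promoters (H3K4me3 high: 4 units), amplitudes jittered ~10% per dataset
  to emulate between-cell-line variation;
* multi-dataset collections sharing a configurable fraction (default 0.5)
  of their enhancers, the rest private per dataset.

What the generator does **not** emulate: read-sampling noise and
mappability structure of real ChIP-Seq pileups, sequence context beyond
composition (positional motifs, conservation), chromatin-state
transitions, and the genome-scale class imbalance (the testbed is ~1:10
at the bin level). Passing the end-to-end tests therefore demonstrates
that the machinery is wired correctly and can recover a planted signal of
realistic effect size — not that the published real-data accuracy is
reproduced.

## Desk-scale problem sizes

The test suite and the acceptance script run the full pipeline at reduced
sizes chosen as the package's own desk-scale defaults: 2 x 120 kb genomes
(1200 bins), 15 enhancers per dataset, committees of 4 members for the
histone flavor (the published 4 x 1000 configuration is exercised
structurally, not trained) and the full 10-member majority-only committee
for the sequence flavor, with the default hyperparameter grid (~700
round-1 lattice points plus 441 refinement points per member).

# Numerical and design choices

* **Coordinates.** GRanges (1-based, closed) is the in-memory container;
  BED's 0-based half-open convention is translated at I/O only.
* **Bin aggregation.** Mean per-base signal per bin; bases not covered by
  any record contribute 0. The aggregation statistic was not fixed by the
  published description; the mean is the least surprising choice and is
  what the per-base oracle in the tests recomputes.
* **Overlapping signal records.** Last record in file order wins.
* **Constant attributes.** A constant column min-max normalizes to 0
  (avoids 0/0); within-subset constant columns are left unscaled by
  libsvm with a suppressed warning.
* **Empty k-mer denominators.** A sequence with no valid window yields an
  all-zero frequency block; an all-ambiguous sequence is an error.
* **Negative-region length matching.** Lengths are bootstrap-resampled
  from the positive length multiset, then the positive minimum and
  maximum are forced into the sample, so min/max match exactly and the
  mean concentrates (within ~5% for >= 50 positives). Draws overlapping
  an exclusion region are rejected, with a configurable cap (default
  1000 x the requested count) to guarantee termination.
* **Remainders.** When a class does not divide evenly into `nParts`,
  the remainder rows go to the last parts, one each.
* **Merging predictions.** Only bookended positive bins merge (gap 0);
  a region's score is the mean probability of its constituent bins.
* **Majority ties.** An exact tie votes negative (conservative).
* **Single-committee aggregation.** With one first-layer committee the
  aggregator consumes the 10 individual member votes by default
  (`vistaPooled = FALSE`); feeding the single pooled vote fraction
  instead is a configuration switch. The individual votes retain more
  information, which is why they are the default.
* **ANN training.** `nnet` with cross-entropy loss, weight decay 1e-3,
  up to 300 iterations, seeded initialization — enough to make the tiny
  aggregation problems (<= 10 inputs) deterministic and reproducible
  from the seed.
* **Determinism.** Every sampling, partitioning, tuning and training
  entry point takes an integer seed and is bitwise reproducible from
  (inputs, seed); committee members are independent, so training order
  is irrelevant.

# Evaluation

`classificationMetrics` reports sensitivity, specificity, accuracy, PPV
(defined as 0 when nothing is predicted positive) and GM.
`rocPrCurves` sweeps the distinct score values (predict positive at
score >= threshold), so the ROC starts at (0,0), ends at (1,1), and its
trapezoidal AUC equals the Mann-Whitney pairwise statistic — an identity
the tests verify against an independent quadratic oracle.

Genome-wide predictions are validated by base-pair overlap with external
support: with A = predicted bases overlapping the support set, B = total
predicted bases, C = total support bases and D = predicted bases
overlapping promoter candidates (the intersection of Pol II and TBP
peaks),

PPV = A/B, Jaccard = A/(B+C-A), F1 = 2A/(B+C), POF = D/B.

Jaccard = F1/(2-F1) algebraically; the tests enforce it. Methods compared
across several such tests are aggregated by ranking each test (ties share
the minimum rank — the published tables handle ties inconsistently, so
the rule is fixed here) and averaging rank positions; lower is better.

# Known limitations

* The exhaustive 11-mark subset search (`featureSubsetSearch`) screens
  subsets with a single fixed-hyperparameter SVM per dataset, not a full
  committee — adequate for ranking subsets, not for absolute GM values.
* The ANN aggregator is a single hidden layer by design; no deeper
  topologies.
* Signal I/O is the bedGraph/wiggle text dialect; the binary bigWig
  container is out of scope.
* Interval semantics are strandless throughout.
* The published genome-wide percentages depend on the genome size used,
  which the original tables do not print; all genome fractions here are
  computed against the user-supplied chromosome-size table.
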