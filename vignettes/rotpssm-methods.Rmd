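---
title: "PSSM descriptors, 2DPCA and Rotation Forests for PPI prediction"
author: "rotpssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSSM descriptors, 2DPCA and Rotation Forests for PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotpssm)
```

## The problem

Most of a proteome's interactions are unknown, and experimental screens
(two-hybrid, mass spectrometry) are expensive and noisy.  Sequence-based
prediction asks: given only the amino-acid sequences of two proteins,
do they interact?  `rotpssm` implements one complete answer: represent
each protein by its evolutionary profile, compress the profile into a
fixed-length descriptor with two-dimensional PCA, and classify the
concatenated pair descriptor with a Rotation Forest ensemble.

## Protein representation

A protein of N residues is represented by its Position-Specific Scoring
Matrix: the N × 20 integer matrix of log-odds scores produced by an
iterative PSI-BLAST search (defaults here: e-value 0.001, 3 iterations),
where entry (i, j) scores how favourably residue i is substituted by
amino-acid type j across the protein's family.  `read_pssm()` parses the
PSI-BLAST ASCII dialect, consuming only the 20 log-odds columns; the
weighted-percentage block and the trailing K/λ statistics are ignored.
Non-standard residues (X, B, Z, U) are parsed like any other so the row
count always equals the sequence length.  Raw log-odds are used as-is; a
sigmoid squashing option exists (`sigmoid = TRUE`) but is off by
default, since the integer scores are what the profile search reports.

**Length standardization.** 2DPCA needs same-shape samples, but proteins
differ in length.  The package standardizes each profile to its
length-normalized Gram matrix A = MᵀM / N.  This 20 × 20 symmetric PSD
matrix captures amino-acid co-conservation, is comparable across
proteins of any length, and does not privilege any particular sequence
position.  The alternative of cropping/zero-padding rows to a fixed
count is available (`fixed_transform = "pad_truncate"`) but is
length-biased and not the default.

## Two-dimensional PCA

Given standardized matrices V₁…V_N, the mean V̄ and the total scatter
matrix

G_t = (1/N) Σᵢ (Vᵢ − V̄)ᵀ(Vᵢ − V̄)

are accumulated; G_t is symmetric PSD by construction (the package
symmetrizes against floating-point rounding and checks the spectrum in
its tests).  The projection axes maximizing the scatter criterion
J(X) = Xᵀ G_t X are the leading unit eigenvectors of G_t; a protein's
descriptor stacks the d projections F_k = (V − V̄) X_k column-major into
a vector of length 20·d.  Numerical conventions, chosen for exact
reproducibility across platforms:

* eigenvectors get a fixed sign (first nonzero coordinate positive);
* ties and near-degeneracies are resolved by the deterministic ordering
  of the symmetric eigensolver;
* projections are centered by V̄.  The scatter criterion is defined on
  centered data, and centering gives the invariants "the mean matrix
  projects to zero" and "the full basis is a Frobenius isometry", both
  enforced in the test suite.  Uncentered projection is available
  (`center = FALSE`) for comparison.

**Choice of d.**  There is no canonical component count for this
descriptor family; `d = 20` (the full, lossless basis) is the package
default, so nothing is discarded unless the user asks for it.  The
synthetic benchmark shipped with the package uses `d = 5`: its latent
interaction structure has low rank (4 clusters), the top few axes carry
essentially all between-cluster scatter, and 2 × 20 × 5 = 200 pair
features keep the small tree ensemble (L = 2) effective, whereas the
full 800-feature coding measurably dilutes it.  Users working with real
profiles should treat d as the main tuning knob and pick it by the
eigenvalue spectrum of G_t.

A protein pair (a, b) is coded as the concatenation [F(a) ‖ F(b)] in
pair-list order; the coding is deliberately order-sensitive and the
order is documented rather than symmetrized.

## Rotation Forest

The classifier is an ensemble of L unpruned CART trees (Gini impurity,
grown by `rpart` with cp = 0, minsplit = 2, minbucket = 1).  For each
tree:

1. the n pair features are split uniformly at random into K disjoint
   subsets of near-equal size (remainder spread one per subset);
2. for each subset, a non-empty random subset of classes is drawn (each
   class kept with probability 1/2, resampled while empty), all samples
   of those classes are pooled, and a fraction (default 0.75) of the
   pool is drawn **without replacement**;
3. PCA is run on the drawn samples restricted to the subset's columns,
   keeping **all** components, so the per-subset loading block is square
   and orthonormal and the rotation loses no information;
4. the blocks form a sparse block-diagonal n × n rotation matrix, rows
   and columns indexed in the original feature order (entries outside
   the blocks are exactly zero), and the tree is trained on X · G.

The sampling in step 2 is drawn without replacement because the
fraction-1.0 limit should coincide exactly with full-data PCA — a
property the test suite verifies against an independent SVD oracle —
and because the subsample's only role is to diversify the rotations,
not to estimate variance.  The PCA centers its sample block when
computing loadings, but the stored rotation applies the loadings to
uncentered features, following the classical Rotation Forest
formulation.

Prediction uses average combination: each tree's leaf class counts are
Laplace-smoothed (+1, so confidences are never degenerate 0/1 and ROC
sweeps have no spurious ties) and averaged,
λ_j(x) = (1/L) Σᵢ d_{i,j}(x Gᵢ); the predicted label is the argmax with
exact ties broken toward the lowest class index.  `K = 20`, `L = 2` are
the defaults, the reported grid-search optimum for this descriptor.
Everything is a deterministic function of the seed: identical seeds
give bit-identical partitions, rotations and predictions.

## Evaluation protocol

`five_fold_cv()` implements the standard protocol: a seeded shuffle
within each label followed by round-robin dealing yields stratified
folds whose per-class sizes differ by at most one.  Per fold, the 2DPCA
basis is fitted **on the training folds' proteins only**, both splits
are projected with it, and the forest is fitted on the training pairs.
Fitting the basis inside the fold is a deliberate leakage-free choice —
fitting it on all proteins up front would inflate the estimates — and a
test asserts the fitted basis is bit-identical whether or not the test
proteins exist at all.

Metrics: accuracy, sensitivity, precision, and MCC from the confusion
counts (positive class = interacting), with two conventions: MCC is 0
whenever a denominator factor is zero, and precision is NaN (excluded
from aggregation, with a warning) when nothing is predicted positive.
ROC curves sweep the positive-class confidence λ₁; AUC is trapezoidal
and equals the tie-corrected Mann–Whitney U statistic, which the tests
check on random instances to 1e-10.  Fold metrics are aggregated as
mean ± sample (n−1) standard deviation.  `cross_species_eval()` fits
basis and model on one dataset and tests on another; when the test set
contains only positive pairs — common for independent PPI sets — it
reports accuracy (which then equals sensitivity) and flags precision,
MCC and AUC unavailable.

## The synthetic benchmark

The generator emulates the *structure* of a golden-standard PPI
benchmark, not its biology.  Each protein belongs to one of
`n_clusters` latent functional clusters (4 by default, standing in for
subcellular compartments); its latent profile is
u = δ·c_cluster + w with c, w standard normal in 20 dimensions.
Interacting pairs are sampled within clusters, non-interacting pairs
across clusters, exactly balanced; PSSM rows are normal draws around u
(sd `noise_sd` = 2 log-odds units), rounded and clipped to the
PSI-BLAST score range [−10, 12].  Default scale: 80 proteins, 250 pairs
per class, lengths 50–120 — a desk-scale analogue of the balanced
benchmark layout in which each protein participates in several pairs.

The separation δ is the single detectability dial.  At δ = 3 the
benchmark is strongly learnable (five-fold mean accuracy above 0.95 at
the shipped configuration); at δ = 0 the labels are pure noise and the
pipeline sits at chance AUC; AUC grows monotonically in between.  All
three behaviours are asserted in the test suite (10 seeds per
condition, one-standard-error slack on the monotonicity), alongside a
label-permutation null.

What passing these tests shows: the descriptor chain preserves latent
similarity structure, the classifier detects it, the protocol does not
leak, and nothing is degenerate.  What it does not show: performance on
real evolutionary profiles.  Real PSSMs have position-dependent
structure, heavy-tailed score distributions, homology between proteins,
and negatives that are not cleanly separated by compartment — none of
which the latent-cluster model imitates.  Benchmarks on real data
require PSI-BLAST profiles against a large database and curated
interaction sets, which the package deliberately treats as external
inputs.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 500-pair
cross-validation benchmarks, 150-pair transfer tests, 50-set oracle
sweeps, 1000-table metric sweeps.  These sizes give stable means (the
stochastic checks use 5–10 seeds and band or 1-s.e. criteria) while
keeping the whole suite around a minute.  Every stochastic routine
takes an explicit integer seed and restores the caller's RNG state, so
results are reproducible end to end and independent of call order.

## Known limitations

* Binary classification only; the average-combination rule generalizes
  to more classes but is untested beyond two.
* The Gram standardization discards residue order entirely; motifs and
  domain architecture are invisible to it.
* `run_psiblast()` is a thin wrapper — building profile databases,
  redundancy filtering of benchmark pairs (e.g. sequence-identity
  thresholds), and negative-set curation are out of scope.
* With L = 2 trees the ensemble's variance is visible across seeds;
  users who care more about stability than the reported optimum should
  raise L.
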