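# rotpssm

Sequence-based prediction of protein–protein interactions (PPIs) from
evolutionary profiles.  `rotpssm` is for computational biologists who want
to classify protein pairs as interacting or non-interacting using nothing
but amino-acid sequence: no structures, no annotations, no network
topology.

## The method

Each protein is represented by its Position-Specific Scoring Matrix
(PSSM), the N × 20 matrix of per-residue log-odds substitution scores
ε<sub>i,j</sub> produced by PSI-BLAST (e-value 0.001, 3 iterations)
against a large protein database.  The pipeline then has three stages:

1. **Profile standardization.** Variable-length profiles are reduced to a
   fixed 20 × 20 Gram matrix A = MᵀM / N, a length-stable summary of
   amino-acid co-conservation.

2. **Two-dimensional PCA (2DPCA).**  Working directly on the matrices
   (never vectorizing them), the total scatter matrix

   G<sub>t</sub> = (1/N) Σ<sub>i</sub> (V<sub>i</sub> − V̄)ᵀ(V<sub>i</sub> − V̄)

   is accumulated over the training proteins, and the descriptor of a
   protein is the projection F<sub>k</sub> = (V − V̄) X<sub>k</sub>,
   k = 1…d, onto the leading d unit eigenvectors of G<sub>t</sub>.  A
   pair is coded by concatenating its two protein descriptors.

3. **Rotation Forest.**  An ensemble of L CART trees; each tree sees the
   pair features transformed by its own sparse block-diagonal rotation
   matrix, built from per-feature-subset PCAs on class-and-sample
   subsamples (K disjoint subsets, all components kept).  Test pairs are
   scored by average combination of the trees' leaf class frequencies,
   λ<sub>j</sub>(x) = (1/L) Σ<sub>i</sub> d<sub>i,j</sub>(x G<sub>i</sub>),
   and evaluated with accuracy, sensitivity, precision, Matthews
   correlation coefficient (MCC) and ROC-AUC under stratified five-fold
   cross-validation.

The defaults K = 20 feature subsets and L = 2 trees are the grid-search
optimum reported for this descriptor family.

## Worked example

The package ships a seeded generator that emulates a golden-standard
benchmark: latent functional clusters of proteins, interacting pairs
drawn within clusters, non-interacting pairs across clusters (the
subcellular-compartment convention for negatives), PSSM-like integer
profiles around each protein's latent 20-vector.

```r
library(rotpssm)

ds <- generate_synthetic_dataset(synthetic_config(separation = 3, seed = 7))
ds
#> pair_dataset: 500 pairs (250 interacting, 250 non-interacting), 80 proteins

report <- five_fold_cv(ds, pipeline_config(d = 5), seed = 7)
report
#> Testing set  Accu.(%)   Sen.(%)  Prec.(%)    MCC(%)    AUC(%)
#> 1               96.00    100.00     92.59     92.30     99.60
#> 2               94.00     94.00     94.00     88.00     98.20
#> 3               98.00    100.00     96.15     96.08    100.00
#> 4               98.00    100.00     96.15     96.08     99.92
#> 5               95.00    100.00     90.91     90.45     98.54
#> Average     96.20 +/- 1.79  98.80 +/- 2.68  93.96 +/- 2.28  92.58 +/- 3.54  99.25 +/- 0.83
```

Each row is one held-out fold; the descriptor basis is refitted on each
fold's training proteins only, so no test information leaks into the
features.  The Average row is the mean ± sample standard deviation over
folds — at separation δ = 3 the pipeline recovers the interaction
structure almost perfectly, while at δ = 0 (no structure) it stays at
chance (AUC ≈ 0.5).

Real PSSM files produced by `psiblast -out_ascii_pssm` are read with
`read_pssm()`, pair lists with `read_pair_list()`; `run_psiblast()`
wraps a local PSI-BLAST installation to build profiles from FASTA
sequences.  A thin CLI covers the same workflow from the shell:

```sh
inst/cli/rotpssm synth --out data/ --seed 7
inst/cli/rotpssm cv --pairs data/pairs.tsv --pssm-dir data/ --d 5 --seed 7 --out report.json
inst/cli/rotpssm train --pairs data/pairs.tsv --pssm-dir data/ --out model.rds
inst/cli/rotpssm predict --model model.rds --pairs other/pairs.tsv --pssm-dir other/
```

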