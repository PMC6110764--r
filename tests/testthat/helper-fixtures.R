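# Shared fixtures and independent oracles used across the test files.

# Random integer PSSM in the PSI-BLAST log-odds range.
random_pssm <- function(n_rows, id = "prot", seed = 1L) {
  withr::with_seed(seed,
    pssm(matrix(sample(-10:12, n_rows * 20L, replace = TRUE), n_rows, 20L),
         id))
}

# Small in-memory pair dataset for protocol tests.  With 4 latent
# clusters, n_prot proteins yield about n_prot^2/8 within-cluster pairs,
# which bounds n_per_class.
tiny_pair_dataset <- function(n_prot = 20L, n_per_class = 20L, seed = 1L,
                              separation = 3) {
  generate_synthetic_dataset(
    synthetic_config(n_proteins = n_prot, n_pairs_per_class = n_per_class,
                     length_range = c(30L, 60L), separation = separation,
                     seed = seed))
}

# The pipeline configuration used for the synthetic benchmark throughout
# the suite: full defaults except d = 5 retained 2DPCA components.
benchmark_config <- function(...) pipeline_config(d = 5L, ...)

# --- independent oracles -------------------------------------------------

# Gram standardization by naive triple loop.
oracle_gram <- function(m) {
  n <- nrow(m); out <- matrix(0, 20L, 20L)
  for (a in 1:20) for (b in 1:20) {
    s <- 0
    for (i in seq_len(n)) s <- s + m[i, a] * m[i, b]
    out[a, b] <- s / n
  }
  out
}

# 2DPCA basis by an independent route: stack the centered matrices and
# take the right singular vectors of the tall matrix B; the eigenvalues
# of G_t = B'B / N are the squared singular values / N.
oracle_2dpca <- function(matrices) {
  n <- length(matrices)
  vbar <- Reduce(`+`, matrices) / n
  b <- do.call(rbind, lapply(matrices, function(v) v - vbar))
  sv <- svd(b)
  p <- ncol(b)
  vals <- rep(0, p)
  vals[seq_along(sv$d)] <- sv$d^2 / n
  list(mean = vbar, eigenvalues = vals, axes = sv$v)
}

# PCA loadings of a data block by SVD of the centered matrix (independent
# of the covariance-eigen route used in the package).
oracle_pca_loadings <- function(block) {
  cen <- sweep(block, 2L, colMeans(block))
  v <- svd(cen, nu = 0, nv = ncol(block))$v
  # same deterministic sign convention as the package
  for (k in seq_len(ncol(v))) {
    nz <- which(abs(v[, k]) > 1e-12)
    if (length(nz) && v[nz[1L], k] < 0) v[, k] <- -v[, k]
  }
  v
}

# Tie-corrected Mann-Whitney U normalization: concordant pairs plus half
# ties over P*N, by explicit pairwise comparison.
oracle_auc_u <- function(scores, actual) {
  pos <- scores[actual == 1L]; neg <- scores[actual == 0L]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Per-element confusion counting loop.
oracle_confusion <- function(predicted, actual) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(predicted)) {
    if (actual[i] == 1L) {
      if (predicted[i] == 1L) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (predicted[i] == 1L) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Check the MCC against Eq-level exact integer arithmetic: with counts
# bounded so all products stay below 2^53, verify sign(mcc) and
# mcc^2 * den == num^2 exactly (both sides integers).
check_mcc_exact <- function(mcc, tp, fp, tn, fn, tol = 1e-10) {
  # doubles represent these integer products exactly (all below 2^53)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  num <- tp * tn - fp * fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(mcc == 0)
  abs(mcc^2 * den - num^2) <= tol * max(1, num^2) &&
    (num == 0 || sign(mcc) == sign(num))
}

# Column-wise equality up to sign (for eigenvector comparisons).
expect_equal_up_to_sign <- function(a, b, tol = 1e-8) {
  for (k in seq_len(ncol(a))) {
    d <- min(max(abs(a[, k] - b[, k])), max(abs(a[, k] + b[, k])))
    expect_lt(d, tol)
  }
}
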