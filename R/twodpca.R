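#' Standardize a variable-length PSSM to a 20 x 20 matrix
#'
#' Proteins have different lengths, so their N x 20 PSSMs cannot be
#' averaged directly.  The package standardizes each profile to the
#' length-normalized Gram matrix A = M'M / N (M the N x 20 score matrix),
#' a 20 x 20 symmetric positive semi-definite summary of amino-acid
#' co-conservation that is stable in scale across protein lengths.  An
#' alternative \code{method = "pad_truncate"} crops or zero-pads the
#' profile rows to a fixed count instead.
#'
#' @param x a \code{\link{pssm}} object.
#' @param method \code{"gram"} (default) or \code{"pad_truncate"}.
#' @param target_rows row count for \code{method = "pad_truncate"}.
#' @param sigmoid if \code{TRUE}, squash raw log-odds through
#'   \code{1/(1+exp(-s))} before standardizing; off by default (raw
#'   log-odds are used as-is).
#' @return A 20 x 20 (or \code{target_rows} x 20) numeric matrix with
#'   attribute \code{protein_id}.
#' @export
pssm_to_fixed <- function(x, method = c("gram", "pad_truncate"),
                          target_rows = 20L, sigmoid = FALSE) {
  stopifnot(inherits(x, "pssm"))
  method <- match.arg(method)
  m <- matrix(as.numeric(x), nrow(x), 20L)
  if (sigmoid) m <- 1 / (1 + exp(-m))
  out <- switch(method,
    gram = crossprod(m) / nrow(m),
    pad_truncate = {
      if (nrow(m) >= target_rows) m[seq_len(target_rows), , drop = FALSE]
      else rbind(m, matrix(0, target_rows - nrow(m), 20L))
    })
  attr(out, "protein_id") <- attr(x, "protein_id")
  out
}

#' Fit a two-dimensional PCA projection basis
#'
#' Two-dimensional PCA operates on matrix-valued samples without
#' vectorizing them.  Given fixed-size matrices \eqn{V_1, \dots, V_N}, it
#' computes the mean \eqn{\bar V} and the total scatter matrix
#' \deqn{G_t = \frac{1}{N} \sum_i (V_i - \bar V)^T (V_i - \bar V),}
#' a 20 x 20 symmetric PSD matrix.  The projection axes maximizing the
#' scatter criterion \eqn{J(X) = X^T G_t X} are the leading unit
#' eigenvectors of \eqn{G_t}; the first \code{d} of them form the basis.
#'
#' The eigenvector sign is fixed so the first nonzero coordinate of each
#' axis is positive, making the basis deterministic across platforms.
#'
#' @param matrices list of same-shape numeric matrices (rows x 20), e.g.
#'   from \code{\link{pssm_to_fixed}}.
#' @param d number of retained components, 1..20 (default 20, the full
#'   basis).
#' @return An object of class \code{"twodpca_basis"} with elements
#'   \code{mean_matrix}, \code{axes} (20 x d, orthonormal columns),
#'   \code{eigenvalues} (all 20, nonincreasing), \code{scatter_matrix}
#'   and \code{d}.
#' @examples
#' mats <- replicate(5, matrix(rnorm(400), 20, 20), simplify = FALSE)
#' b <- fit_2dpca(mats, d = 3)
#' sum(b$eigenvalues) - sum(diag(b$scatter_matrix))  # ~ 0
#' @export
fit_2dpca <- function(matrices, d = 20L) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("fit_2dpca needs at least 2 matrices")
  dims <- unique(lapply(matrices, dim))
  if (length(dims) != 1L)
    stop("all matrices must have identical dimensions")
  p <- dims[[1L]][2L]
  if (!is.numeric(d) || length(d) != 1L || d < 1L || d > p)
    stop("d must be between 1 and ", p)
  d <- as.integer(d)
  n <- length(matrices)
  vbar <- Reduce(`+`, matrices) / n
  gt <- matrix(0, p, p)
  for (v in matrices) {
    cv <- v - vbar
    gt <- gt + crossprod(cv)
  }
  gt <- gt / n
  gt <- (gt + t(gt)) / 2  # enforce exact symmetry against rounding
  eg <- eigen(gt, symmetric = TRUE)
  axes <- fix_axis_signs(eg$vectors[, seq_len(d), drop = FALSE])
  structure(list(mean_matrix = vbar,
                 axes = axes,
                 eigenvalues = eg$values,
                 scatter_matrix = gt,
                 d = d),
            class = "twodpca_basis")
}

# Deterministic sign convention: first coordinate of each column that is
# nonzero (beyond tolerance) is made positive.
fix_axis_signs <- function(v, tol = 1e-12) {
  for (k in seq_len(ncol(v))) {
    nz <- which(abs(v[, k]) > tol)
    if (length(nz) && v[nz[1L], k] < 0) v[, k] <- -v[, k]
  }
  v
}

#' @export
print.twodpca_basis <- function(x, ...) {
  cat(sprintf("2DPCA basis: d = %d axes over %d-column matrices\n",
              x$d, nrow(x$axes)))
  ev <- x$eigenvalues
  cat(sprintf("  scatter trace %.4g; top eigenvalue share %.1f%%\n",
              sum(ev), 100 * ev[1L] / max(sum(ev), .Machine$double.eps)))
  invisible(x)
}

#' Project a fixed-size matrix onto a 2DPCA basis
#'
#' Computes the principal-component features
#' \eqn{F_k = (V - \bar V) X_k, k = 1 \dots d} and flattens them
#' column-major (all 20 entries of \eqn{F_1}, then \eqn{F_2}, ...) into a
#' descriptor of length \code{20 * d}.  Centering by the training mean
#' matches the scatter criterion the axes optimize; it can be disabled.
#'
#' @param matrix_20 a matrix with as many columns as the basis axes have
#'   rows (20 for PSSM Gram matrices).
#' @param basis a \code{\link{fit_2dpca}} result.
#' @param center subtract the basis mean matrix first (default TRUE).
#' @return Numeric feature vector of length \code{nrow(matrix_20) * d},
#'   with attribute \code{protein_id} when the input carries one.
#' @export
project_fixed <- function(matrix_20, basis, center = TRUE) {
  stopifnot(inherits(basis, "twodpca_basis"))
  if (!all(dim(matrix_20) == dim(basis$mean_matrix)))
    stop("matrix dimensions ", paste(dim(matrix_20), collapse = "x"),
         " do not match the basis (",
         paste(dim(basis$mean_matrix), collapse = "x"), ")")
  v <- if (center) matrix_20 - basis$mean_matrix else matrix_20
  f <- as.vector(v %*% basis$axes)  # column-major: F_1 block, F_2 block, ...
  attr(f, "protein_id") <- attr(matrix_20, "protein_id")
  f
}

#' @rdname project_fixed
#' @param x a \code{\link{pssm}} object; convenience wrapper applying
#'   \code{\link{pssm_to_fixed}} then \code{project_fixed}.
#' @param ... passed to \code{pssm_to_fixed}.
#' @export
project_pssm <- function(x, basis, center = TRUE, ...) {
  project_fixed(pssm_to_fixed(x, ...), basis, center = center)
}

#' Concatenate two protein descriptors into a pair feature
#'
#' A protein pair is coded by concatenating the two proteins' descriptor
#' vectors in pair-list order (first-listed protein first); the coding is
#' order-sensitive.
#'
#' @param fa,fb feature vectors produced by the same basis.
#' @param label optional binary label (1 interacting, 0 not).
#' @return Numeric vector of length \code{length(fa) + length(fb)}, with
#'   attribute \code{label} when given.
#' @export
pair_feature <- function(fa, fb, label = NULL) {
  if (length(fa) != length(fb))
    stop("pair members have different descriptor lengths (",
         length(fa), " vs ", length(fb), "); were they projected with ",
         "the same basis?")
  v <- c(as.numeric(fa), as.numeric(fb))
  if (!is.null(label)) {
    if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
    attr(v, "label") <- as.integer(label)
  }
  v
}

#' Build the pair-feature design matrix for a dataset
#'
#' Projects every protein in the dataset once and assembles the
#' (pairs x 2*20*d) design matrix row per pair, plus the label vector.
#'
#' @param dataset a \code{\link{pair_dataset}}.
#' @param basis a fitted \code{\link{fit_2dpca}} basis.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{x} (numeric matrix) and \code{y} (integer
#'   labels).
#' @export
pair_design_matrix <- function(dataset, basis, config = pipeline_config()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  feats <- lapply(dataset$pssms, function(p)
    project_fixed(pssm_to_fixed(p, method = config$fixed_transform,
                                sigmoid = config$sigmoid),
                  basis, center = config$center))
  pr <- dataset$pairs
  x <- t(vapply(seq_len(nrow(pr)), function(i)
    pair_feature(feats[[pr$id_a[i]]], feats[[pr$id_b[i]]]),
    numeric(2L * length(feats[[1L]]))))
  list(x = x, y = as.integer(pr$label))
}

#' Serialize / restore a 2DPCA basis
#'
#' The basis (mean matrix, axes, eigenvalues, scatter matrix, d) is stored
#' in a single version-stamped RDS archive; the round-trip is bit-exact.
#'
#' @param basis a \code{twodpca_basis}.
#' @param path archive path.
#' @return \code{read_basis} returns the restored \code{twodpca_basis}.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "twodpca_basis"))
  saveRDS(list(format = "rotpssm_basis", version = 1L, basis = basis),
          path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rotpssm_basis"))
    stop(path, " is not a rotpssm basis archive")
  obj$basis
}
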