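#' Random disjoint feature partition
#'
#' Splits the feature indices 1..n uniformly at random into K disjoint
#' subsets covering all of 1..n.  When K does not divide n, the remaining
#' n mod K features are spread one per subset, so every subset has
#' floor(n/K) or ceiling(n/K) members.
#'
#' @param n number of features.
#' @param K number of subsets, 1 <= K <= n.
#' @return List of K integer index vectors.
#' @export
make_partition <- function(n, K) {
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("K = ", K, " exceeds the number of features n = ", n)
  perm <- sample.int(n)
  sizes <- rep(n %/% K, K)
  r <- n %% K
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  split(perm, rep(seq_len(K), times = sizes))
}

# PCA loadings (all components) of a sample block: columns are the unit
# eigenvectors of the column-centered covariance, in nonincreasing
# eigenvalue order, sign-fixed for determinism.
pca_loadings <- function(block) {
  cen <- scale(block, center = TRUE, scale = FALSE)
  cv <- crossprod(cen) / max(nrow(block) - 1L, 1L)
  cv <- (cv + t(cv)) / 2
  fix_axis_signs(eigen(cv, symmetric = TRUE)$vectors)
}

#' Build one sparse rotation matrix
#'
#' For each feature subset of the partition, a non-empty subset of classes
#' is chosen, all samples of those classes are pooled and a fraction of
#' them drawn (without replacement) to form the PCA sample set; PCA over
#' the subset's columns yields a block of loadings (all components kept).
#' The blocks are placed on the diagonal of an n x n matrix whose
#' rows/columns are indexed in the original feature order, so every entry
#' outside the blocks is exactly zero and the rotated design is
#' \code{X \%*\% rotation}.
#'
#' @param x numeric sample matrix (T x n), T >= 2.
#' @param y class labels, length T.
#' @param partition a \code{\link{make_partition}} result for n features.
#' @param bootstrap_fraction fraction of the pooled class samples used for
#'   each subset's PCA (drawn without replacement), in (0, 1].
#' @param class_subset_rule \code{"random"} or \code{"all"}; see
#'   \code{\link{pipeline_config}}.
#' @return An n x n rotation matrix with attribute \code{partition}.
#' @export
build_rotation <- function(x, y, partition, bootstrap_fraction = 0.75,
                           class_subset_rule = "random") {
  stopifnot(is.matrix(x), nrow(x) >= 2L, nrow(x) == length(y))
  n <- ncol(x)
  idx_all <- sort(unname(unlist(partition)))
  if (!identical(idx_all, seq_len(n)))
    stop("partition does not cover features 1..", n)
  classes <- sort(unique(y))
  rot <- matrix(0, n, n)
  for (subset in partition) {
    subset <- sort(subset)  # canonical within-block feature order
    rows <- subset_sample_rows(y, classes, bootstrap_fraction,
                               class_subset_rule)
    rot[subset, subset] <- pca_loadings(x[rows, subset, drop = FALSE])
  }
  attr(rot, "partition") <- partition
  rot
}

# Choose the PCA sample rows for one feature subset: random non-empty
# class subset, then a without-replacement draw of the given fraction.
# If the draw would leave < 2 samples, the class choice is retried a
# bounded number of times and finally all samples are used.
subset_sample_rows <- function(y, classes, fraction, rule,
                               max_retries = 10L) {
  for (attempt in seq_len(max_retries)) {
    keep <- if (rule == "all") rep(TRUE, length(classes))
            else stats::runif(length(classes)) < 0.5
    if (!any(keep)) next
    pool <- which(y %in% classes[keep])
    take <- floor(fraction * length(pool))
    if (take >= 2L)
      return(sort(sample(pool, take)))
    if (rule == "all") break
  }
  seq_along(y)  # fallback: every sample
}

#' Fit a Rotation Forest ensemble
#'
#' Trains L CART decision trees, each on the design matrix rotated by its
#' own sparse block matrix: per tree, the features are randomly
#' partitioned into K disjoint subsets, each subset gets a PCA fitted on a
#' class-and-sample subsample of the training data, and the per-subset
#' loadings (all components, so no information is lost) form the diagonal
#' blocks of the rotation.  The per-tree rotations differ, which is the
#' ensemble's diversity mechanism.  Trees are grown unpruned with Gini
#' impurity (\pkg{rpart}).
#'
#' @param x numeric sample matrix (T x n), T >= 4.
#' @param y binary labels (0/1 or a 2-level factor); both classes must be
#'   present.
#' @param K feature subsets per tree (default 20); requires n >= K.
#' @param L number of trees (default 2).
#' @param bootstrap_fraction see \code{\link{build_rotation}}.
#' @param seed integer seed; the fit is fully deterministic given it.
#' @param class_subset_rule see \code{\link{pipeline_config}}.
#' @return An object of class \code{"rotation_forest"}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200), 50), matrix(rnorm(200, 3), 50))
#' y <- rep(c(0, 1), each = 50)
#' fit <- rotation_forest(x, y, K = 2, L = 2, seed = 7)
#' mean(predict(fit, x) == y)
#' @export
rotation_forest <- function(x, y, K = 20L, L = 2L,
                            bootstrap_fraction = 0.75, seed = 1L,
                            class_subset_rule = "random") {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 4L) stop("need at least 4 training samples")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  n <- ncol(x)
  if (K > n)
    stop("K = ", K, " exceeds the ", n, " features; choose a smaller K")
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L)
    stop("training labels contain a single class")
  yf <- factor(as.character(y), levels = classes)

  with_seed(seed, {
    partitions <- vector("list", L)
    rotations <- vector("list", L)
    trees <- vector("list", L)
    ctrl <- rpart::rpart.control(cp = 0, minsplit = 2L, minbucket = 1L,
                                 xval = 0L, maxcompete = 0L,
                                 maxsurrogate = 0L)
    for (i in seq_len(L)) {
      partitions[[i]] <- make_partition(n, K)
      rotations[[i]] <- build_rotation(x, as.character(y), partitions[[i]],
                                       bootstrap_fraction,
                                       class_subset_rule)
      xr <- x %*% rotations[[i]]
      df <- as.data.frame(xr)
      names(df) <- paste0("f", seq_len(n))
      df$.class <- yf
      trees[[i]] <- rpart::rpart(.class ~ ., data = df, method = "class",
                                 control = ctrl)
    }
    structure(list(trees = trees, rotations = rotations,
                   partitions = partitions, classes = classes,
                   n_features = n,
                   config = list(K = as.integer(K), L = as.integer(L),
                                 bootstrap_fraction = bootstrap_fraction,
                                 class_subset_rule = class_subset_rule,
                                 seed = as.integer(seed))),
              class = "rotation_forest")
  })
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf(
    "rotation_forest: %d trees, K = %d feature subsets, %d features, classes {%s}\n",
    x$config$L, x$config$K, x$n_features, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Per-class confidences by average combination
#'
#' Each test sample is rotated by every tree's own rotation matrix and the
#' tree's leaf class frequencies (Laplace-smoothed with +1 so confidences
#' are never degenerate 0/1) are averaged across the ensemble:
#' \eqn{\lambda_j(x) = \frac{1}{L}\sum_i d_{i,j}(x G_i)}.  Each row sums
#' to 1.
#'
#' @param model a fitted \code{\link{rotation_forest}}.
#' @param x sample matrix with \code{model$n_features} columns.
#' @return Numeric matrix (samples x classes), columns named by class.
#' @export
predict_confidence <- function(model, x) {
  stopifnot(inherits(model, "rotation_forest"))
  if (!is.matrix(x)) x <- matrix(x, ncol = model$n_features)
  if (ncol(x) != model$n_features)
    stop("x has ", ncol(x), " columns but the model was trained on ",
         model$n_features, " features")
  nc <- length(model$classes)
  acc <- matrix(0, nrow(x), nc)
  for (i in seq_along(model$trees)) {
    xr <- x %*% model$rotations[[i]]
    df <- as.data.frame(xr)
    names(df) <- paste0("f", seq_len(ncol(x)))
    m <- stats::predict(model$trees[[i]], newdata = df, type = "matrix")
    counts <- m[, 1L + seq_len(nc), drop = FALSE]  # leaf class counts
    acc <- acc + (counts + 1) / (rowSums(counts) + nc)
  }
  lambda <- acc / length(model$trees)
  colnames(lambda) <- model$classes
  lambda
}

#' Predict pair labels
#'
#' Assigns each sample the class with the largest average-combination
#' confidence; exact ties go to the lowest class index.
#'
#' @param object a fitted \code{\link{rotation_forest}}.
#' @param x sample matrix with \code{n_features} columns.
#' @param ... unused.
#' @return Vector of predicted class labels (same label set as training).
#' @export
predict.rotation_forest <- function(object, x, ...) {
  lambda <- predict_confidence(object, x)
  pick <- apply(lambda, 1L, which.max)  # first max = lowest class index
  object$classes[pick]
}

#' Serialize / restore a Rotation Forest model
#'
#' Single version-stamped RDS archive holding the config, partitions,
#' rotation matrices and fitted trees; the round-trip is bit-exact.
#' Loading rejects archives of another format version; prediction rejects
#' inputs whose feature count differs from the training matrix.
#'
#' @param model a \code{rotation_forest}.
#' @param path archive path.
#' @return \code{load_model} returns the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(list(format = "rotpssm_model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rotpssm_model") ||
      !identical(obj$version, 1L))
    stop(path, " is not a version-1 rotpssm model archive")
  obj$model
}
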