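#' Confusion counts for binary predictions
#'
#' Counts with class 1 (interacting pair) as the positive class: TP is a
#' correctly predicted positive, FP a negative predicted positive, TN a
#' correctly predicted negative, FN a positive predicted negative.
#'
#' @param predicted,actual equal-length binary (0/1) label vectors.
#' @return A \code{"confusion_counts"} list with elements \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}.
#' @export
confusion <- function(predicted, actual) {
  predicted <- as.integer(as.character(predicted))
  actual <- as.integer(as.character(actual))
  if (length(predicted) != length(actual))
    stop("predicted and actual lengths differ")
  if (!all(c(predicted, actual) %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  structure(list(tp = sum(predicted == 1L & actual == 1L),
                 fp = sum(predicted == 1L & actual == 0L),
                 tn = sum(predicted == 0L & actual == 0L),
                 fn = sum(predicted == 0L & actual == 1L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes the four standard binary summaries:
#' \deqn{Accu = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Sen = TP/(TP+FN)}
#' \deqn{Prec = TP/(TP+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' When any MCC denominator factor is zero the MCC is defined as 0 (the
#' standard limit convention).  Precision with TP + FP = 0 is undefined
#' and returned as \code{NaN} with a warning; callers exclude it from
#' aggregation.
#'
#' @param counts a \code{\link{confusion}} result, or a list with
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @return Named numeric vector \code{accuracy}, \code{sensitivity},
#'   \code{precision}, \code{mcc}.
#' @export
classification_metrics <- function(counts) {
  # double precision: the MCC denominator product overflows 32-bit
  # integers long before counts become large
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  accuracy <- (tp + tn) / total
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NaN
  if (tp + fp > 0) {
    precision <- tp / (tp + fp)
  } else {
    warning("no positive predictions; precision undefined (NaN)")
    precision <- NaN
  }
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(den2)
  c(accuracy = accuracy, sensitivity = sensitivity,
    precision = precision, mcc = mcc)
}

#' ROC curve and area under it
#'
#' Sweeps a decision threshold over the unique confidence scores, tracing
#' (false positive rate, true positive rate) points from (0,0) to (1,1),
#' and integrates by the trapezoidal rule.  Tied scores move the curve
#' diagonally, so the AUC equals the tie-corrected Mann-Whitney
#' U-statistic (concordant pairs plus half the ties, over P*N).
#'
#' @param scores positive-class confidences.
#' @param actual binary 0/1 labels; both classes must be present.
#' @return List with \code{auc} and \code{roc} (data.frame of
#'   \code{threshold}, \code{fpr}, \code{tpr}).
#' @export
roc_auc <- function(scores, actual) {
  actual <- as.integer(as.character(actual))
  if (length(scores) != length(actual))
    stop("scores and actual lengths differ")
  if (!all(actual %in% c(0L, 1L))) stop("labels must be binary 0/1")
  p <- sum(actual == 1L); n <- sum(actual == 0L)
  if (p == 0L || n == 0L)
    stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr) + 1L)
  for (k in seq_along(thr)) {
    pos <- scores >= thr[k]
    tpr[k + 1L] <- sum(pos & actual == 1L) / p
    fpr[k + 1L] <- sum(pos & actual == 0L) / n
  }
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr))
}

# Stratified fold assignment: within each label, shuffle then deal
# round-robin, so per-label fold sizes differ by at most one.
stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < folds)
      stop("class ", lab, " has only ", length(idx), " pairs; too few for ",
           folds, "-fold cross-validation (reduce `folds`)")
    idx <- sample(idx)
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

# Fit the descriptor basis on a set of proteins only (training proteins
# of a fold), never on test-fold proteins: leakage-free by construction.
fit_basis_for_ids <- function(dataset, ids, config) {
  mats <- lapply(dataset$pssms[ids], pssm_to_fixed,
                 method = config$fixed_transform, sigmoid = config$sigmoid)
  fit_2dpca(unname(mats), d = config$d)
}

# Shared per-split work: fit basis + forest on the training pairs,
# score the test pairs.
evaluate_split <- function(train_pairs, test_pairs, pssms, config, seed,
                           fold_index = NA_integer_) {
  train_ids <- unique(c(train_pairs$id_a, train_pairs$id_b))
  train_ds <- pair_dataset(train_pairs, pssms[train_ids])
  basis <- fit_basis_for_ids(train_ds, train_ids, config)
  tr <- pair_design_matrix(train_ds, basis, config)
  model <- rotation_forest(tr$x, tr$y, K = config$K, L = config$L,
                           bootstrap_fraction = config$bootstrap_fraction,
                           seed = seed,
                           class_subset_rule = config$class_subset_rule)
  test_ids <- unique(c(test_pairs$id_a, test_pairs$id_b))
  test_ds <- pair_dataset(test_pairs, pssms[test_ids])
  te <- pair_design_matrix(test_ds, basis, config)
  lambda <- predict_confidence(model, te$x)
  scores <- lambda[, "1"]
  predicted <- as.integer(model$classes[apply(lambda, 1L, which.max)])
  fold_result(predicted, te$y, scores, fold_index)
}

# Assemble a per-fold result record; metrics follow classification_metrics
# and AUC is only computed when both classes appear in the test labels.
fold_result <- function(predicted, actual, scores, fold_index) {
  counts <- confusion(predicted, actual)
  met <- suppressWarnings(classification_metrics(counts))
  single_class <- length(unique(actual)) < 2L
  if (single_class) {
    # all-positive (or all-negative) test set: only accuracy is meaningful
    # (it equals sensitivity when all pairs are positive)
    met["precision"] <- NaN
    met["mcc"] <- NaN
  }
  auc <- if (single_class) NaN else roc_auc(scores, actual)$auc
  structure(list(fold_index = fold_index,
                 counts = counts,
                 accuracy = unname(met["accuracy"]),
                 sensitivity = unname(met["sensitivity"]),
                 precision = unname(met["precision"]),
                 mcc = unname(met["mcc"]),
                 auc = auc,
                 scores = scores,
                 actual = actual,
                 single_class_test = single_class),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "fold %s: Accu %.2f%%  Sen %.2f%%  Prec %.2f%%  MCC %.2f%%  AUC %.2f%%\n",
    ifelse(is.na(x$fold_index), "-", x$fold_index),
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$precision,
    100 * x$mcc, 100 * x$auc))
  if (x$single_class_test)
    cat("  (single-class test set: accuracy equals sensitivity;",
        "precision/MCC/AUC unavailable)\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' The protocol behind every reported benchmark: pairs are divided into
#' folds of almost equal size with both interacting and non-interacting
#' pairs in each (per-label round-robin after a seeded shuffle).  For each
#' fold, the 2DPCA basis is fitted on the training folds' proteins only,
#' both splits are projected, a Rotation Forest is fitted on the training
#' pairs and evaluated on the held-out pairs.  Metrics are reported per
#' fold and aggregated as mean plus/minus the sample (n-1) standard
#' deviation.
#'
#' @param dataset a \code{\link{pair_dataset}}.
#' @param config a \code{\link{pipeline_config}}; \code{config$folds}
#'   sets the fold count (default 5).
#' @param seed integer seed controlling the shuffle and every model fit.
#' @return An \code{"evaluation_report"} with elements \code{folds} (list
#'   of per-fold results), \code{mean}, \code{sd}, \code{config},
#'   \code{seed}.
#' @export
five_fold_cv <- function(dataset, config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  pr <- dataset$pairs
  if (nrow(pr) < 10L) stop("need at least 10 pairs for cross-validation")
  if (length(unique(pr$label)) < 2L)
    stop("both labels must be present")
  folds <- config$folds
  with_seed(seed, {
    assignment <- stratified_folds(pr$label, folds)
    results <- vector("list", folds)
    for (f in seq_len(folds)) {
      results[[f]] <- evaluate_split(pr[assignment != f, , drop = FALSE],
                                     pr[assignment == f, , drop = FALSE],
                                     dataset$pssms, config,
                                     seed = seed + f, fold_index = f)
    }
    evaluation_report(results, config, seed)
  })
}

# Aggregate fold metrics as mean and sample sd, skipping NaN sentinels
# (undefined precision/AUC on degenerate folds) with a warning upstream.
evaluation_report <- function(folds, config, seed) {
  metric_names <- c("accuracy", "sensitivity", "precision", "mcc", "auc")
  tab <- vapply(folds, function(f)
    unlist(f[metric_names]), numeric(length(metric_names)))
  means <- apply(tab, 1L, function(v) mean(v[is.finite(v)]))
  sds <- apply(tab, 1L, function(v) stats::sd(v[is.finite(v)]))
  names(means) <- names(sds) <- metric_names
  structure(list(folds = folds, mean = means, sd = sds,
                 config = config, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%-11s %9s %9s %9s %9s %9s\n", "Testing set", "Accu.(%)",
              "Sen.(%)", "Prec.(%)", "MCC(%)", "AUC(%)"))
  for (f in x$folds)
    cat(sprintf("%-11s %9.2f %9.2f %9.2f %9.2f %9.2f\n",
                f$fold_index, 100 * f$accuracy, 100 * f$sensitivity,
                100 * f$precision, 100 * f$mcc, 100 * f$auc))
  cat(sprintf("%-11s %s\n", "Average",
              paste(sprintf("%.2f +/- %.2f", 100 * x$mean, 100 * x$sd),
                    collapse = "  ")))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an \code{evaluation_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    seed = report$seed,
    config = unclass(report$config),
    folds = lapply(report$folds, function(f)
      list(fold = f$fold_index,
           counts = unclass(f$counts),
           accuracy = f$accuracy, sensitivity = f$sensitivity,
           precision = f$precision, mcc = f$mcc, auc = f$auc)),
    mean = as.list(report$mean),
    sd = as.list(report$sd))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export pooled ROC points as TSV
#'
#' Pools the per-fold test scores of a report and writes the resulting
#' ROC sweep as tab-separated \code{threshold}, \code{fpr}, \code{tpr}.
#'
#' @param report an \code{evaluation_report}.
#' @param path output path.
#' @return The pooled ROC data.frame, invisibly.
#' @export
write_roc_tsv <- function(report, path) {
  scores <- unlist(lapply(report$folds, `[[`, "scores"))
  actual <- unlist(lapply(report$folds, `[[`, "actual"))
  roc <- roc_auc(scores, actual)$roc
  utils::write.table(roc, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(roc)
}

#' Train on one species, test on another
#'
#' Cross-species protocol: the descriptor basis and the Rotation Forest
#' are fitted on the training dataset only, then applied to an independent
#' test dataset (possibly a disjoint protein universe).  Independent PPI
#' test sets often contain only interacting pairs; in that case accuracy
#' coincides with sensitivity, and precision/MCC/AUC are flagged
#' unavailable (\code{NaN}).
#'
#' @param train,test \code{\link{pair_dataset}} objects.
#' @param config a \code{\link{pipeline_config}}.
#' @param seed integer seed for the model fit.
#' @return A single fold result for the test set.
#' @export
cross_species_eval <- function(train, test, config = pipeline_config(),
                               seed = 1L) {
  stopifnot(inherits(train, "pair_dataset"), inherits(test, "pair_dataset"))
  if (nrow(test$pairs) == 0L) stop("empty test dataset")
  with_seed(seed,
    evaluate_split(train$pairs, test$pairs,
                   c(train$pssms, test$pssms[setdiff(names(test$pssms),
                                                     names(train$pssms))]),
                   config, seed = seed))
}
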