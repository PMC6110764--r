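# Metrics, ROC/AUC, the cross-validation protocol, cross-species mode.

test_that("confusion counts match a per-element counting loop", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  cc <- confusion(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(cc$tp + cc$tn, 0L)
  withr::with_seed(31, {
    pred <- sample(0:1, 100, replace = TRUE)
    act <- sample(0:1, 100, replace = TRUE)
  })
  expect_equal(unclass(confusion(pred, act))[c("tp", "fp", "tn", "fn")],
               oracle_confusion(pred, act))
  expect_error(confusion(c(1, 0), c(1)), "lengths differ")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("the four summary formulas are exact, with stated conventions", {
  m <- classification_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))

  m <- classification_metrics(list(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(m[["accuracy"]], 0.5)
  expect_equal(m[["mcc"]], 0)

  # frozen example checked by exact integer arithmetic on the identity
  # mcc^2 * denominator == numerator^2
  m <- classification_metrics(list(tp = 94, fp = 0, tn = 100, fn = 6))
  expect_equal(m[["accuracy"]], 194 / 200)
  expect_equal(m[["sensitivity"]], 94 / 100)
  expect_equal(m[["precision"]], 1)
  expect_true(check_mcc_exact(m[["mcc"]], 94, 0, 100, 6))
  expect_equal(m[["mcc"]], 9400 / sqrt(94 * 100 * 100 * 106),
               tolerance = 1e-12)

  # zero-denominator MCC convention and undefined precision
  expect_equal(
    suppressWarnings(
      classification_metrics(list(tp = 0, fp = 0, tn = 10, fn = 5)))[["mcc"]],
    0)
  expect_warning(
    out <- classification_metrics(list(tp = 0, fp = 0, tn = 10, fn = 5)),
    "precision undefined")
  expect_true(is.nan(out[["precision"]]))
  expect_error(classification_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "empty")
})

test_that("trapezoidal AUC equals the tie-corrected U statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- 20L
      scores <- round(runif(n), 2)  # rounding forces ties
      actual <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
      r <- roc_auc(scores, actual)
      expect_equal(r$auc, oracle_auc_u(scores, actual), tolerance = 1e-10)
      # curve runs from (0,0) to (1,1) monotonically
      expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
      expect_equal(tail(r$roc$fpr, 1), 1)
      expect_equal(tail(r$roc$tpr, 1), 1)
      expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    }
  })
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(19, {
    scores <- rnorm(60)
    actual <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(actual, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, actual)$auc, ref, tolerance = 1e-10)
})

test_that("cross-validation is stratified, aggregated exactly, reproducible", {
  ds <- tiny_pair_dataset(n_prot = 20L, n_per_class = 20L, seed = 3)
  cfg <- pipeline_config(d = 2, folds = 5)
  rep1 <- five_fold_cv(ds, cfg, seed = 5)

  expect_length(rep1$folds, 5L)
  # per-class fold sizes differ by at most one
  for (lab in 0:1) {
    sizes <- vapply(rep1$folds, function(f) sum(f$actual == lab),
                    numeric(1))
    expect_lte(diff(range(sizes)), 1)
  }
  # the report mean is exactly the arithmetic mean of fold metrics
  for (met in c("accuracy", "sensitivity", "precision", "mcc", "auc")) {
    vals <- vapply(rep1$folds, `[[`, numeric(1), met)
    expect_equal(rep1$mean[[met]], mean(vals), tolerance = 1e-12)
    expect_equal(rep1$sd[[met]], sd(vals), tolerance = 1e-12)
  }
  # metric consistency: every fold re-derives from its own counts
  for (f in rep1$folds) {
    m <- suppressWarnings(classification_metrics(f$counts))
    expect_identical(f$accuracy, unname(m["accuracy"]))
    expect_identical(f$sensitivity, unname(m["sensitivity"]))
    expect_identical(f$mcc, unname(m["mcc"]))
  }
  rep2 <- five_fold_cv(ds, cfg, seed = 5)
  expect_equal(rep1$mean, rep2$mean, tolerance = 0)

  expect_error(five_fold_cv(ds, pipeline_config(folds = 30), seed = 1),
               "too few")
})

test_that("the per-fold basis never sees test-fold proteins", {
  ds <- tiny_pair_dataset(n_prot = 16L, n_per_class = 20L, seed = 4)
  train_ids <- names(ds$pssms)[1:10]
  cfg <- pipeline_config(d = 3)
  full <- rotpssm:::fit_basis_for_ids(ds, train_ids, cfg)
  # drop every other protein from the lookup entirely: identical basis
  pruned <- pair_dataset(
    ds$pairs[ds$pairs$id_a %in% train_ids &
               ds$pairs$id_b %in% train_ids, , drop = FALSE],
    ds$pssms[train_ids])
  expect_identical(rotpssm:::fit_basis_for_ids(pruned, train_ids, cfg),
                   full)
})

test_that("report serialization writes valid JSON and pooled ROC TSV", {
  ds <- tiny_pair_dataset(n_prot = 16L, n_per_class = 15L, seed = 6)
  rep <- five_fold_cv(ds, pipeline_config(d = 2), seed = 2)
  jf <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, jf)
  parsed <- jsonlite::read_json(jf)
  expect_length(parsed$folds, 5L)
  expect_equal(parsed$mean$accuracy, rep$mean[["accuracy"]])
  tf <- withr::local_tempfile(fileext = ".tsv")
  roc <- write_roc_tsv(rep, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(roc))
  out <- capture.output(print(rep))
  expect_match(out[1], "Accu")
  expect_match(out[length(out)], "Average")
})

test_that("cross-species mode trains on one universe, tests on another", {
  cfg_train <- synthetic_config(n_proteins = 40L, n_pairs_per_class = 75L,
                                separation = 3, seed = 51,
                                center_seed = 99, id_prefix = "A")
  cfg_test <- synthetic_config(n_proteins = 30L, n_pairs_per_class = 50L,
                               separation = 3, seed = 52,
                               center_seed = 99, id_prefix = "B")
  train <- generate_synthetic_dataset(cfg_train)
  test <- generate_synthetic_dataset(cfg_test)
  expect_length(intersect(names(train$pssms), names(test$pssms)), 0L)

  res <- cross_species_eval(train, test, benchmark_config(), seed = 3)
  resub <- cross_species_eval(train, train, benchmark_config(), seed = 3)
  expect_gte(resub$accuracy, res$accuracy)  # resubstitution sanity
  expect_gt(res$accuracy, 0.5)              # transfer beats chance

  # all-positive test set: accuracy collapses to sensitivity, the rest
  # is flagged unavailable
  pos <- test$pairs[test$pairs$label == 1L, , drop = FALSE]
  pos_ids <- unique(c(pos$id_a, pos$id_b))
  pos_ds <- pair_dataset(pos, test$pssms[pos_ids])
  res_pos <- cross_species_eval(train, pos_ds, benchmark_config(),
                                seed = 3)
  expect_true(res_pos$single_class_test)
  cc <- res_pos$counts
  expect_equal(res_pos$accuracy, cc$tp / (cc$tp + cc$fn))
  expect_equal(res_pos$accuracy, res_pos$sensitivity)
  expect_true(is.nan(res_pos$precision) && is.nan(res_pos$mcc) &&
                is.nan(res_pos$auc))
  expect_error(cross_species_eval(train, pair_dataset(
    test$pairs[0, ], test$pssms), benchmark_config(), seed = 1), "empty")
})

test_that("cross-species transfer is well above chance on shared structure", {
  accs <- sapply(1:10, function(s) {
    tr <- generate_synthetic_dataset(synthetic_config(
      n_proteins = 40L, n_pairs_per_class = 75L, separation = 3,
      seed = 300 + s, center_seed = 777, id_prefix = "A"))
    te <- generate_synthetic_dataset(synthetic_config(
      n_proteins = 30L, n_pairs_per_class = 75L, separation = 3,
      seed = 600 + s, center_seed = 777, id_prefix = "B"))
    cross_species_eval(tr, te, benchmark_config(), seed = s)$accuracy
  })
  expect_gte(mean(accs), 0.7)  # at least 0.2 above the 0.5 chance level
})
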