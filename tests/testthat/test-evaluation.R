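test_that("confusion metrics match hand-evaluated closed forms", {
  m <- compute_metrics(c(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_identical(c(m$sn, m$sp, m$ac, m$mcc), c(1, 1, 1, 1))

  # everything called positive on a balanced set
  m <- compute_metrics(c(tp = 10, tn = 0, fp = 10, fn = 0))
  expect_identical(c(m$sn, m$sp, m$ac), c(1, 0, 0.5))
  expect_identical(m$mcc, 0)
  expect_true("mcc" %in% m$undefined)

  m <- compute_metrics(c(tp = 3, tn = 2, fp = 2, fn = 1))
  expect_equal(m$sn, 0.75)
  expect_equal(m$sp, 0.5)
  expect_equal(m$ac, 0.625)
  expect_equal(m$mcc, (3 * 2 - 2 * 1) / sqrt(5 * 4 * 4 * 3), tolerance = 1e-12)

  expect_error(compute_metrics(c(tp = -1, tn = 1, fp = 1, fn = 1)),
               "non-negative")
  # no positives at all: Sn undefined, not an exception
  m <- compute_metrics(c(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m$sn))
  expect_true("sn" %in% m$undefined)
})

test_that("confusion_counts tallies calls against truth", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_identical(cc, c(tp = 2L, tn = 1L, fp = 1L, fn = 1L))
})

test_that("ROC/AUC reproduce analytic cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  rc <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
})

test_that("threshold-sweep AUC equals the rank-statistic AUC including ties", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(10:120, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2))   # deliberately tied scores
    expect_equal(roc_auc(s, y, "trapezoid"), roc_auc(s, y, "rank"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(60), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("folds partition the data and stratification keeps the class ratio", {
  set.seed(29)
  y <- rep(c(1L, 0L), c(40, 200))
  for (k in c(6L, 8L, 10L)) {
    folds <- make_folds(y, k, stratified = TRUE, seed = 3)
    expect_identical(sort(unique(folds)), seq_len(k))
    expect_identical(length(folds), length(y))
    sizes_pos <- table(folds[y == 1L])
    sizes_neg <- table(folds[y == 0L])
    expect_lte(max(sizes_pos) - min(sizes_pos), 1)
    expect_lte(max(sizes_neg) - min(sizes_neg), 1)
  }
  # k = n degenerates to one sample per fold, the LOO partition
  folds <- make_folds(rep(c(0L, 1L), 5), k = 10, seed = 1)
  expect_identical(sort(tabulate(folds)), rep(1L, 10))
  expect_error(make_folds(y, 1), "k must be")
  expect_error(make_folds(y, length(y) + 1L), "k must be")
})

test_that("LOO refits the chain per held-out sample and pools the scores", {
  ds <- toy_separable(12, seed = 31)
  # plug-in MI is noisy at n = 24, so give the selector room: 20 features
  res <- run_loo(ds, pipeline = tiny_pipeline(20), seed = 1)
  expect_length(res$scores, nrow(ds))
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  expect_gt(res$auc, 0.9)   # trivially separable
  expect_s3_class(res$metrics, "metric_set")
  expect_error(run_loo(ds$peptide[1:3], c(1L, 1L, 1L)), "both classes")
})

test_that("repeated k-fold reports pooled and per-fold AUC conventions", {
  ds <- toy_separable(12, seed = 37)
  res <- run_kfold(ds, pipeline = tiny_pipeline(),
                   plan = cv_plan("kfold", k = 3, repeats = 2, seed = 5))
  expect_length(res$auc_per_repeat, 2L)
  expect_equal(res$auc, mean(res$auc_per_repeat))
  expect_false(is.na(res$auc_sd))
  expect_true(is.numeric(res$auc_per_fold_mean))
  # vertically averaged ROC on the fixed FPR grid
  expect_identical(nrow(res$roc), 101L)
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_true(all(res$roc$tpr >= 0 & res$roc$tpr <= 1))
  expect_error(run_kfold(ds, plan = cv_plan(k = 100)), "k exceeds")
})

test_that("k-fold is reproducible from its seeds", {
  ds <- toy_separable(10, seed = 41)
  plan <- cv_plan("kfold", k = 3, repeats = 2, seed = 11)
  r1 <- run_kfold(ds, pipeline = tiny_pipeline(), plan = plan)
  r2 <- run_kfold(ds, pipeline = tiny_pipeline(), plan = plan)
  expect_identical(r1$auc_per_repeat, r2$auc_per_repeat)
  expect_identical(r1$metrics, r2$metrics)
})
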