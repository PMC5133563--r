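# Cross-validation protocols, confusion-matrix metrics and ROC/AUC.

#' Confusion counts from calls and truth
#'
#' @param predicted Predicted labels (0/1 or positive/negative).
#' @param truth True labels.
#' @return Named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- normalize_labels(predicted)
  y <- normalize_labels(truth)
  stopifnot(length(p) == length(y))
  c(tp = sum(p == 1L & y == 1L), tn = sum(p == 0L & y == 0L),
    fp = sum(p == 1L & y == 0L), fn = sum(p == 0L & y == 1L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Ac = (TP+TN)/total`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator does not raise an error: Sn/Sp become `NA` and MCC is
#' reported as 0 with the affected metrics listed in `undefined`.
#'
#' @param counts Named vector or list with `tp`, `tn`, `fp`, `fn`
#'   (see [confusion_counts()]); alternatively pass the four counts as
#'   separate arguments.
#' @param tn,fp,fn Individual counts when `counts` is the `tp` scalar.
#' @return An object of class `metric_set`: `sn`, `sp`, `ac`, `mcc`,
#'   `counts`, `undefined`.
#' @export
#' @examples
#' compute_metrics(c(tp = 3, tn = 2, fp = 2, fn = 1))  # Sn 0.75, Sp 0.5
compute_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.null(tn)) counts <- c(tp = counts, tn = tn, fp = fp, fn = fn)
  counts <- unlist(counts)[c("tp", "tn", "fp", "fn")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative tp/tn/fp/fn")
  tp <- counts["tp"]; tn <- counts["tn"]
  fp <- counts["fp"]; fn <- counts["fn"]
  total <- sum(counts)
  if (total == 0) stop("at least one sample is required")
  undefined <- character(0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sn"); NA_real_ }
  sp <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "sp"); NA_real_ }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom)
         else { undefined <- c(undefined, "mcc"); 0 }
  structure(list(sn = unname(sn), sp = unname(sp),
                 ac = unname((tp + tn) / total), mcc = unname(mcc),
                 counts = counts, undefined = undefined),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn = %.4f  Sp = %.4f  Ac = %.4f  MCC = %.4f\n",
              x$sn, x$sp, x$ac, x$mcc))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (predict positive
#' when score >= threshold), from all-negative (0, 0) to all-positive
#' (1, 1).
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return Data frame with `threshold`, `fpr`, `tpr`, sorted by increasing
#'   FPR.
#' @export
roc_curve <- function(scores, labels) {
  y <- normalize_labels(labels)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2L) stop("both classes are required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  tps <- cumsum(ys == 1L); fps <- cumsum(ys == 0L)
  # collapse tied scores to a single operating point
  last <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(threshold = c(Inf, scores[ord][last]),
             fpr = c(0, fps[last] / nneg),
             tpr = c(0, tps[last] / npos))
}

#' Area under the ROC curve
#'
#' `method = "trapezoid"` integrates the threshold-sweep curve of
#' [roc_curve()]; `method = "rank"` computes the normalized Mann-Whitney
#' statistic (probability that a random positive outscores a random
#' negative, ties counted 1/2). The two are mathematically identical and
#' serve as an internal cross-check.
#'
#' @inheritParams roc_curve
#' @param method `"trapezoid"` (default) or `"rank"`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
roc_auc <- function(scores, labels, method = c("trapezoid", "rank")) {
  method <- match.arg(method)
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes are required for AUC")
  if (method == "trapezoid") {
    rc <- roc_curve(scores, y)
    sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
  } else {
    r <- rank(scores)  # midranks handle ties as 1/2
    npos <- sum(y == 1L); nneg <- sum(y == 0L)
    (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
}

#' Stratified fold assignment
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param stratified Preserve the class ratio (within one sample) in each
#'   fold? Default `TRUE`.
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
make_folds <- function(labels, k, stratified = TRUE, seed = 1L) {
  y <- normalize_labels(labels)
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L || k > n) stop(sprintf("k must be in [2, %d]", n))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  folds <- integer(n)
  if (stratified) {
    # rotate the fold counter across classes so that k close to n still
    # covers every fold (k = n then degenerates to the LOO partition)
    offset <- 0L
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  } else {
    folds[sample(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

#' Cross-validation plan
#'
#' @param scheme `"kfold"` or `"loo"`.
#' @param k Folds for `"kfold"`; 6, 8 and 10 in the reference protocol.
#' @param repeats Number of reshuffled repetitions for `"kfold"`, default
#'   30 (the reference protocol); each repeat draws its folds from a seed
#'   derived from `seed`.
#' @param stratified Stratify folds by class, default `TRUE`.
#' @param seed Master seed.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("kfold", "loo"), k = 6L, repeats = NULL,
                    stratified = TRUE, seed = 1L) {
  scheme <- match.arg(scheme)
  if (is.null(repeats)) repeats <- if (scheme == "kfold") 30L else 1L
  stopifnot(repeats >= 1L)
  structure(list(scheme = scheme, k = as.integer(k),
                 repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_plan")
}

# Deterministic seed derivation: every repeat / fold / stage gets its own
# stream from the master seed, all below 2^31.
derive_seed <- function(seed, i) {
  (as.integer(seed) + 1664525 * as.integer(i)) %% .Machine$integer.max
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For every sample the complete chain (constant-feature mask, mRMR
#' selection, optional scaler, SVM) is refitted on the remaining samples
#' and the held-out window is scored; the pooled scores give one ROC/AUC.
#' With `selection_scope = "dataset"` in the pipeline, the mask and
#' selection are instead fitted once on the full data (leaky; recorded in
#' the result).
#'
#' @param peptides Windows (character vector or data frame with `peptide`
#'   and `label`).
#' @param labels Binary labels; taken from the data frame when omitted.
#' @param pipeline A [mal_pipeline()].
#' @param seed Master seed.
#' @return List of class `cv_result`: `scores`, `labels`, `auc`, `roc`,
#'   `metrics` (at the configured threshold), `scheme`.
#' @export
run_loo <- function(peptides, labels = NULL, pipeline = mal_pipeline(),
                    seed = 1L) {
  d <- as_labeled_windows(peptides, labels)
  n <- length(d$labels)
  if (n < 2L || length(unique(d$labels)) < 2L)
    stop("LOO requires >= 2 samples with both classes")
  x <- encode_dataset(d$peptides, pipeline)
  scores <- numeric(n)
  shared <- if (pipeline$selection_scope == "dataset")
    fit_encoded(x, d$labels, pipeline, seed = seed) else NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    chain <- if (is.null(shared)) {
      fit_encoded(x[tr, , drop = FALSE], d$labels[tr], pipeline,
                  seed = derive_seed(seed, i))
    } else {
      ch <- shared
      xs <- apply_reduction(x[tr, , drop = FALSE], ch$mask)
      if (!is.null(ch$scaler)) xs <- apply_minmax(xs, ch$scaler)
      ch$svm <- train_svm(xs[, ch$selection$indices, drop = FALSE],
                          d$labels[tr], pipeline$svm,
                          seed = derive_seed(seed, i))
      ch
    }
    scores[i] <- predict_encoded(chain, x[i, , drop = FALSE], pipeline)
  }
  finalize_cv(scores, d$labels, pipeline, scheme = "loo")
}

#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' Within each repeat, the chain is refitted on every training fold and the
#' held-out fold is scored; the scores of one repeat are pooled into a
#' single ROC/AUC. Reported across repeats: mean and standard deviation of
#' the pooled AUC, the mean of per-fold AUCs (both conventions are
#' emitted), averaged threshold metrics, and a vertically averaged ROC on a
#' fixed 101-point FPR grid.
#'
#' @inheritParams run_loo
#' @param plan A [cv_plan()].
#' @return List of class `cv_result` with `auc` (mean pooled AUC),
#'   `auc_per_repeat`, `auc_sd`, `auc_per_fold_mean`, `metrics`, `roc`
#'   (averaged), `scheme`, `k`, `repeats`.
#' @export
run_kfold <- function(peptides, labels = NULL, pipeline = mal_pipeline(),
                      plan = cv_plan()) {
  d <- as_labeled_windows(peptides, labels)
  n <- length(d$labels)
  if (plan$k > n) stop("k exceeds the number of samples")
  x <- encode_dataset(d$peptides, pipeline)
  shared <- if (pipeline$selection_scope == "dataset")
    fit_encoded(x, d$labels, pipeline, seed = plan$seed) else NULL
  grid <- seq(0, 1, by = 0.01)
  auc_rep <- numeric(plan$repeats)
  fold_auc_all <- numeric(0)
  tpr_sum <- numeric(length(grid))
  counts_sum <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (r in seq_len(plan$repeats)) {
    folds <- make_folds(d$labels, plan$k, plan$stratified,
                        seed = derive_seed(plan$seed, r))
    scores <- numeric(n)
    for (f in seq_len(plan$k)) {
      te <- folds == f
      chain <- if (is.null(shared)) {
        fit_encoded(x[!te, , drop = FALSE], d$labels[!te], pipeline,
                    seed = derive_seed(plan$seed, r * 1000L + f))
      } else {
        ch <- shared
        xs <- apply_reduction(x[!te, , drop = FALSE], ch$mask)
        if (!is.null(ch$scaler)) xs <- apply_minmax(xs, ch$scaler)
        ch$svm <- train_svm(xs[, ch$selection$indices, drop = FALSE],
                            d$labels[!te], pipeline$svm,
                            seed = derive_seed(plan$seed, r * 1000L + f))
        ch
      }
      scores[te] <- predict_encoded(chain, x[te, , drop = FALSE], pipeline)
      if (length(unique(d$labels[te])) == 2L)
        fold_auc_all <- c(fold_auc_all, roc_auc(scores[te], d$labels[te]))
    }
    auc_rep[r] <- roc_auc(scores, d$labels)
    rc <- roc_curve(scores, d$labels)
    tpr_sum <- tpr_sum + vapply(grid, function(g) max(rc$tpr[rc$fpr <= g]),
                                numeric(1))
    counts_sum <- counts_sum +
      confusion_counts(as.integer(scores > pipeline$svm$theta), d$labels)
  }
  metrics <- compute_metrics(round(counts_sum / plan$repeats))
  out <- finalize_cv(NULL, d$labels, pipeline, scheme = "kfold")
  out$auc <- mean(auc_rep)
  out$auc_sd <- if (plan$repeats > 1L) sd(auc_rep) else NA_real_
  out$auc_per_repeat <- auc_rep
  out$auc_per_fold_mean <- mean(fold_auc_all)
  out$metrics <- metrics
  out$roc <- data.frame(fpr = grid, tpr = tpr_sum / plan$repeats)
  out$k <- plan$k
  out$repeats <- plan$repeats
  out
}

as_labeled_windows <- function(peptides, labels) {
  if (is.data.frame(peptides)) {
    if (is.null(labels)) labels <- peptides$label
    peptides <- peptides$peptide
  }
  if (is.null(labels)) stop("labels are required")
  list(peptides = peptides, labels = normalize_labels(labels))
}

finalize_cv <- function(scores, labels, pipeline, scheme) {
  out <- list(scheme = scheme,
              selection_scope = pipeline$selection_scope,
              theta = pipeline$svm$theta)
  if (!is.null(scores)) {
    out$scores <- scores
    out$labels <- labels
    out$auc <- roc_auc(scores, labels)
    out$roc <- roc_curve(scores, labels)
    out$metrics <- compute_metrics(
      confusion_counts(as.integer(scores > pipeline$svm$theta), labels))
  }
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  lab <- if (x$scheme == "loo") "LOO"
         else sprintf("%d-fold x %d", x$k, x$repeats)
  cat(sprintf("%s cross-validation: AUC = %.4f", lab, x$auc))
  if (!is.null(x$auc_sd) && !is.na(x$auc_sd))
    cat(sprintf(" (sd %.4f over repeats)", x$auc_sd))
  cat("\n")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
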