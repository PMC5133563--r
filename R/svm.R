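# Probability-output RBF support vector machine (libsvm via e1071).

#' SVM configuration
#'
#' @param gamma RBF kernel width, default 0.0125.
#' @param cost Soft-margin cost C, default 1.
#' @param theta Decision threshold on the positive-class probability,
#'   default 0.5. A window is called positive when
#'   `Pr(positive) > theta`; a probability exactly equal to `theta` is
#'   called negative (conservative tie rule).
#' @param probability Fit the sigmoid probability calibration, default
#'   `TRUE`.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(gamma = 0.0125, cost = 1, theta = 0.5,
                       probability = TRUE) {
  stopifnot(gamma > 0, cost > 0, theta > 0, theta < 1)
  structure(list(gamma = gamma, cost = cost, theta = theta,
                 probability = isTRUE(probability)),
            class = "svm_config")
}

# Low-level RBF-SVM fit on a prepared feature matrix. The probability
# calibration (sigmoid fit on cross-validated decision values inside
# libsvm) consumes R's RNG stream, so the seed is fixed here to make
# refits reproducible.
train_svm <- function(x, y, config = svm_config(), seed = 1L) {
  y <- normalize_labels(y)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fit <- e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
                    scale = FALSE, kernel = "radial",
                    gamma = config$gamma, cost = config$cost,
                    probability = config$probability)
  list(fit = fit, config = config, seed = as.integer(seed),
       class_counts = c(negative = sum(y == 0L), positive = sum(y == 1L)))
}

# Positive-class probabilities (or decision values when the model was
# fitted without calibration) for a prepared feature matrix.
predict_svm_scores <- function(model, x, type = c("probability", "decision")) {
  type <- match.arg(type)
  if (type == "probability" && !model$config$probability)
    stop("model was fitted without probability calibration")
  pr <- predict(model$fit, x, probability = model$config$probability,
                decision.values = TRUE)
  if (type == "probability") {
    p <- attr(pr, "probabilities")
    unname(p[, "1"])
  } else {
    dv <- attr(pr, "decision.values")
    s <- unname(dv[, 1L])
    # orient decision values so larger = more positive
    if (grepl("^0/", colnames(dv)[1L])) -s else s
  }
}

#' Grid-search helper for the SVM cost parameter
#'
#' Cross-validated AUC over a grid of cost values on an already prepared
#' (reduced + selected) feature matrix.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param costs Candidate cost values.
#' @param config Base [svm_config()]; `gamma` and `theta` are kept.
#' @param k Folds, default 5.
#' @param seed RNG seed.
#' @return Data frame of cost and mean cross-validated AUC, best first.
#' @export
tune_cost <- function(x, y, costs = 2^(-3:5), config = svm_config(),
                      k = 5L, seed = 1L) {
  y <- normalize_labels(y)
  folds <- make_folds(y, k = k, stratified = TRUE, seed = seed)
  auc <- vapply(costs, function(cc) {
    cfg <- svm_config(gamma = config$gamma, cost = cc, theta = config$theta,
                      probability = FALSE)
    scores <- numeric(length(y))
    for (f in seq_len(k)) {
      te <- folds == f
      m <- train_svm(x[!te, , drop = FALSE], y[!te], cfg, seed = seed + f)
      scores[te] <- predict_svm_scores(m, x[te, , drop = FALSE], "decision")
    }
    roc_auc(scores, y)
  }, numeric(1))
  out <- data.frame(cost = costs, auc = auc)
  out[order(-out$auc), , drop = FALSE]
}
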