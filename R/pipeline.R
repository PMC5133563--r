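# The full prediction chain: encode -> drop constant features -> mRMR ->
# (optional scaling) -> probability RBF-SVM.

#' Pipeline configuration
#'
#' Collects every tunable of the prediction chain. Defaults follow the
#' published protocol: 16-mer windows, 687-feature encoding, 50 mRMR
#' features, RBF-SVM with `gamma = 0.0125` and threshold 0.5.
#'
#' @param window A [window_config()].
#' @param property_table A `property_table`, default
#'   [default_property_table()].
#' @param kgram_values `"count"` or `"binary"` k-gram features.
#' @param n_features Number of mRMR-selected features, default 50.
#' @param mrmr_scheme `"MID"` or `"MIQ"`.
#' @param discretization A [discretization_scheme()].
#' @param svm An [svm_config()].
#' @param scale Min-max scale each feature to the unit interval after
#'   constant removal? Default `TRUE`: the feature blocks differ in
#'   magnitude by two orders (k-gram counts 0-16 vs. property values in the
#'   hundreds), and an RBF width of `gamma = 0.0125` (about 1 / 50, the
#'   libsvm convention for unit-scaled features) is only meaningful after
#'   scaling — without it the kernel degenerates and ranking performance
#'   collapses. The scaler is fitted on training data only and stored in
#'   the model; set `FALSE` to run on raw features.
#' @param selection_scope `"fold"` (default; the reduction mask and mRMR
#'   selection are refitted inside every cross-validation training fold) or
#'   `"dataset"` (fit once on the full dataset before cross-validation; a
#'   leaky protocol kept available for comparison and clearly recorded in
#'   reports).
#' @return An object of class `mal_pipeline`.
#' @export
mal_pipeline <- function(window = window_config(),
                         property_table = NULL,
                         kgram_values = c("count", "binary"),
                         n_features = 50L,
                         mrmr_scheme = c("MID", "MIQ"),
                         discretization = discretization_scheme(),
                         svm = svm_config(),
                         scale = TRUE,
                         selection_scope = c("fold", "dataset")) {
  kgram_values <- match.arg(kgram_values)
  mrmr_scheme <- match.arg(mrmr_scheme)
  selection_scope <- match.arg(selection_scope)
  if (is.null(property_table)) property_table <- default_property_table()
  stopifnot(inherits(window, "window_config"),
            inherits(svm, "svm_config"),
            inherits(discretization, "discretization_scheme"),
            n_features >= 1L)
  structure(list(window = window, property_table = property_table,
                 kgram_values = kgram_values,
                 n_features = as.integer(n_features),
                 mrmr_scheme = mrmr_scheme, discretization = discretization,
                 svm = svm, scale = isTRUE(scale),
                 selection_scope = selection_scope),
            class = "mal_pipeline")
}

#' @export
print.mal_pipeline <- function(x, ...) {
  cat(sprintf(paste0("mal_pipeline: %d-mer windows, %s k-grams, ",
                     "%d mRMR features (%s), gamma = %g, C = %g, theta = %g, ",
                     "scaling %s, selection per %s\n"),
              x$window$length, x$kgram_values, x$n_features, x$mrmr_scheme,
              x$svm$gamma, x$svm$cost, x$svm$theta,
              if (x$scale) "on" else "off", x$selection_scope))
  invisible(x)
}

encode_dataset <- function(peptides, pipeline) {
  encode_peptides(peptides, table = pipeline$property_table,
                  config = pipeline$window,
                  kgram_values = pipeline$kgram_values)
}

fit_minmax <- function(x) {
  mins <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - mins
  rng[rng == 0] <- 1
  list(mins = mins, range = rng)
}

apply_minmax <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$mins, "-"), 2L, scaler$range, "/")
}

# Fit mask + scaler + selection + SVM on an already-encoded matrix.
fit_encoded <- function(x, y, pipeline, seed = 1L) {
  y <- normalize_labels(y)
  mask <- fit_reduction_mask(x)
  xr <- apply_reduction(x, mask)
  scaler <- NULL
  if (pipeline$scale) {
    scaler <- fit_minmax(xr)
    xr <- apply_minmax(xr, scaler)
  }
  selection <- mrmr_select(xr, y, n = pipeline$n_features,
                           scheme = pipeline$mrmr_scheme,
                           discretization = pipeline$discretization)
  xs <- xr[, selection$indices, drop = FALSE]
  svm_fit <- train_svm(xs, y, pipeline$svm, seed = seed)
  list(mask = mask, scaler = scaler, selection = selection,
       svm = svm_fit, seed = as.integer(seed))
}

predict_encoded <- function(chain, x, pipeline,
                            type = c("probability", "decision")) {
  xr <- apply_reduction(x, chain$mask)
  if (!is.null(chain$scaler)) xr <- apply_minmax(xr, chain$scaler)
  xs <- xr[, chain$selection$indices, drop = FALSE]
  predict_svm_scores(chain$svm, xs, type = match.arg(type))
}

#' Fit the full malonylation-site prediction model
#'
#' Encodes the labeled windows, drops dataset-constant features, selects
#' `n_features` by mRMR and trains the probability RBF-SVM. The returned
#' model carries the complete preprocessing chain, so prediction on new
#' windows reproduces the training-time transformations exactly.
#'
#' @param peptides Character vector of fixed-length windows, or a data
#'   frame with `peptide` (and optionally `label`) columns.
#' @param labels Binary labels (0/1 or positive/negative); taken from the
#'   data frame's `label` column when omitted.
#' @param pipeline A [mal_pipeline()].
#' @param seed RNG seed controlling the SVM probability calibration.
#' @return An object of class `mal_model`.
#' @export
mal_fit <- function(peptides, labels = NULL, pipeline = mal_pipeline(),
                    seed = 1L) {
  if (is.data.frame(peptides)) {
    if (is.null(labels)) labels <- peptides$label
    peptides <- peptides$peptide
  }
  if (is.null(labels)) stop("labels are required")
  labels <- normalize_labels(labels)
  x <- encode_dataset(peptides, pipeline)
  chain <- fit_encoded(x, labels, pipeline, seed = seed)
  structure(c(chain, list(pipeline = pipeline,
                          n_samples = length(labels),
                          class_counts = chain$svm$class_counts)),
            class = "mal_model")
}

#' @export
print.mal_model <- function(x, ...) {
  cat(sprintf("mal_model: trained on %d windows (%d positive / %d negative)\n",
              x$n_samples, x$class_counts["positive"],
              x$class_counts["negative"]))
  cat(sprintf("  %d -> %d features after constant removal; %d selected by mRMR (%s)\n",
              x$mask$n_features, x$mask$n_kept, x$selection$n,
              x$selection$scheme))
  print(x$pipeline)
  invisible(x)
}

#' Positive-class probability for peptide windows
#'
#' @param model A fitted [mal_fit()] model.
#' @param peptides Character vector of windows (or data frame with a
#'   `peptide` column), or an already-encoded 687-column feature matrix.
#' @return Numeric vector of `Pr(positive)` in `[0, 1]`.
#' @export
predict_probability <- function(model, peptides) {
  stopifnot(inherits(model, "mal_model"))
  x <- if (is.matrix(peptides)) peptides else
    encode_dataset(if (is.data.frame(peptides)) peptides$peptide else peptides,
                   model$pipeline)
  predict_encoded(model, x, model$pipeline, type = "probability")
}

#' Classify peptide windows
#'
#' A window is called positive when its probability strictly exceeds
#' `theta`; a probability exactly at `theta` yields a negative call.
#'
#' @param model A fitted [mal_fit()] model.
#' @param peptides Windows as in [predict_probability()].
#' @param theta Decision threshold; defaults to the model's configured
#'   threshold.
#' @return Data frame with `probability` and `call`
#'   (`"positive"`/`"negative"`), plus the peptide string when available.
#' @export
classify <- function(model, peptides, theta = NULL) {
  if (is.null(theta)) theta <- model$pipeline$svm$theta
  stopifnot(theta > 0, theta < 1)
  p <- predict_probability(model, peptides)
  out <- data.frame(probability = p,
                    call = ifelse(p > theta, "positive", "negative"),
                    stringsAsFactors = FALSE)
  pep <- if (is.data.frame(peptides)) peptides$peptide
         else if (is.character(peptides)) peptides else NULL
  if (!is.null(pep)) out <- cbind(data.frame(peptide = pep,
                                             stringsAsFactors = FALSE), out)
  out
}

#' @rdname predict_probability
#' @param object A `mal_model`.
#' @param newdata Windows or encoded matrix.
#' @param type `"probability"` (default) or `"class"`.
#' @param theta Threshold for `type = "class"`.
#' @param ... Ignored.
#' @export
predict.mal_model <- function(object, newdata, type = c("probability", "class"),
                              theta = NULL, ...) {
  type <- match.arg(type)
  if (type == "probability") predict_probability(object, newdata)
  else classify(object, newdata, theta = theta)$call
}

#' Save / load a fitted model archive
#'
#' The archive is a single file holding the SVM state, reduction mask,
#' mRMR selection, pipeline configuration and seed; reloading reproduces
#' predictions exactly.
#'
#' @param model A `mal_model`.
#' @param path Archive path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mal_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mal_model"))
    stop(sprintf("'%s' does not contain a mal_model archive", path))
  model
}
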