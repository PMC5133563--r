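# Minimum-Redundancy-Maximum-Relevance feature selection on mutual
# information, with the discretization needed for continuous features.

#' Discretization scheme for mutual-information estimation
#'
#' Mutual information is estimated on discrete labels, so real-valued
#' features (the physicochemical block) must be discretized first.
#' `"three-state-mean-sigma"` maps values below `mean - alpha * sigma` to
#' state 0, above `mean + alpha * sigma` to state 2 and the rest to state 1
#' (`sigma` is the population standard deviation). `"equal-frequency"` cuts
#' at empirical quantiles into `bins` states. Under method `"auto"`,
#' integer-valued columns (the k-gram counts and position codes) pass
#' through unchanged and only real-valued columns get the three-state
#' treatment.
#'
#' @param method One of `"auto"`, `"three-state-mean-sigma"`,
#'   `"equal-frequency"`, `"none"`.
#' @param alpha Width multiplier for the mean +/- sigma thresholds,
#'   default 1.
#' @param bins Number of bins for `"equal-frequency"`, default 3.
#' @return An object of class `discretization_scheme`.
#' @export
discretization_scheme <- function(method = c("auto", "three-state-mean-sigma",
                                             "equal-frequency", "none"),
                                  alpha = 1, bins = 3L) {
  method <- match.arg(method)
  stopifnot(alpha > 0, bins >= 2L)
  structure(list(method = method, alpha = alpha, bins = as.integer(bins)),
            class = "discretization_scheme")
}

#' Discretize one feature column
#'
#' @param x Numeric vector.
#' @param scheme A [discretization_scheme()]. `"auto"` passes integer-valued
#'   columns through and applies three-state mean +/- sigma otherwise.
#' @return Integer label vector. A zero-variance column yields a single
#'   label everywhere (valid, not an error).
#' @export
#' @examples
#' discretize(c(-10, 0, 10), discretization_scheme(alpha = 0.5))  # 0 1 2
discretize <- function(x, scheme = discretization_scheme()) {
  stopifnot(length(x) > 0L)
  method <- scheme$method
  if (method == "auto")
    method <- if (all(x == round(x))) "none" else "three-state-mean-sigma"
  switch(method,
    "none" = as.integer(x),
    "three-state-mean-sigma" = {
      m <- mean(x)
      s <- sqrt(mean((x - m)^2))  # population sd
      as.integer((x > m - scheme$alpha * s) + (x > m + scheme$alpha * s))
    },
    "equal-frequency" = {
      br <- unique(quantile(x, probs = seq(0, 1, length.out = scheme$bins + 1L)))
      if (length(br) < 2L) return(rep(0L, length(x)))
      as.integer(cut(x, breaks = br, include.lowest = TRUE)) - 1L
    })
}

# Discretize all columns and relabel each to contiguous codes 0..(k-1);
# returns list(codes = integer matrix, k = states per column).
discretize_matrix <- function(x, scheme = discretization_scheme()) {
  p <- ncol(x)
  codes <- matrix(0L, nrow(x), p)
  k <- integer(p)
  for (j in seq_len(p)) {
    lab <- discretize(x[, j], scheme)
    u <- sort(unique(lab))
    codes[, j] <- match(lab, u) - 1L
    k[j] <- length(u)
  }
  list(codes = codes, k = k)
}

#' Plug-in mutual information between two discrete vectors
#'
#' \eqn{I(X;Y) = \sum_{a,b} p(a,b) \log[p(a,b) / (p(a) p(b))]} over the
#' empirical joint distribution, in nats. Symmetric and non-negative; zero
#' whenever either argument is constant.
#'
#' @param x,y Vectors of equal length; coerced to discrete labels.
#' @return Non-negative mutual information in nats.
#' @export
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # log(2)
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  xf <- as.integer(factor(x)) - 1L
  yf <- as.integer(factor(y)) - 1L
  cpp_mi(xf, yf, max(xf) + 1L, max(yf) + 1L)
}

#' Greedy mRMR feature selection
#'
#' Step 1 selects the feature with maximum relevance \eqn{I(f; y)}; each
#' later step selects the unselected feature maximizing
#' relevance \eqn{-} mean MI with the already-selected set (`MID`,
#' the difference form) or relevance / mean MI (`MIQ`, the quotient form).
#' Ties are broken toward the lowest feature index.
#'
#' @param x Numeric feature matrix (columns optionally named).
#' @param y Binary class labels (0/1).
#' @param n Number of features to select, default 50. If `n` exceeds the
#'   number of columns, all are selected with a warning.
#' @param scheme `"MID"` (default) or `"MIQ"`.
#' @param discretization A [discretization_scheme()] applied to `x`.
#' @return An object of class `mrmr_selection`: `indices` (ordered),
#'   `names`, `scheme`, and `table` (rank, feature, relevance, redundancy,
#'   score per step).
#' @export
mrmr_select <- function(x, y, n = 50L, scheme = c("MID", "MIQ"),
                        discretization = discretization_scheme()) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(x), ncol(x) >= 1L, nrow(x) == length(y), n >= 1L)
  y <- normalize_labels(y)
  n <- as.integer(n)
  p <- ncol(x)
  if (n > p) {
    warning(sprintf("n = %d exceeds %d available features; selecting all", n, p))
    n <- p
  }
  d <- discretize_matrix(x, discretization)
  yl <- as.integer(factor(y)) - 1L
  relevance <- cpp_mi_profile(d$codes, yl, d$k, max(yl) + 1L)

  selected <- integer(n)
  red_sum <- numeric(p)        # cumulative MI with selected features
  redundancy <- numeric(n); score <- numeric(n)
  available <- rep(TRUE, p)
  for (t in seq_len(n)) {
    if (t == 1L) {
      sc <- relevance
      red <- numeric(p)
    } else {
      red <- red_sum / (t - 1L)
      sc <- if (scheme == "MID") relevance - red
            else relevance / pmax(red, .Machine$double.eps)
    }
    sc[!available] <- -Inf
    pick <- which.max(sc)      # first maximum = lowest index on ties
    selected[t] <- pick
    redundancy[t] <- red[pick]
    score[t] <- sc[pick]
    available[pick] <- FALSE
    if (t < n)
      red_sum <- red_sum + cpp_mi_profile(d$codes, d$codes[, pick],
                                          d$k, d$k[pick])
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(p))
  structure(list(
    indices = selected,
    names = nm[selected],
    scheme = scheme,
    n = n,
    discretization = discretization,
    table = data.frame(rank = seq_len(n), feature = nm[selected],
                       index = selected, relevance = relevance[selected],
                       redundancy = redundancy, score = score,
                       stringsAsFactors = FALSE)
  ), class = "mrmr_selection")
}

#' @export
print.mrmr_selection <- function(x, ...) {
  cat(sprintf("mrmr_selection: %d features (%s)\n", x$n, x$scheme))
  print(head(x$table, 10L))
  if (x$n > 10L) cat("...\n")
  invisible(x)
}

#' Write an mRMR selection report
#' @param selection An `mrmr_selection`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  stopifnot(inherits(selection, "mrmr_selection"))
  write_tsv(selection$table, path)
}
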