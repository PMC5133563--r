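# Position-frequency summaries and two-sample enrichment of peptide sets.

#' Position-frequency matrix of a peptide set
#'
#' @param peptides Character vector of equal-length windows (or data frame
#'   with a `peptide` column).
#' @param config A [window_config()] (names the positions).
#' @return 21 x L matrix of class `position_frequency_matrix`: empirical
#'   residue frequencies per window position. Rows are the 21-symbol
#'   alphabet (the dummy residue is a real signal at protein termini);
#'   columns are positions `-xi .. +eta` and each sums to 1. Attribute
#'   `n`: number of windows.
#' @export
frequency_matrix <- function(peptides, config = window_config()) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  if (!length(peptides)) stop("at least one window is required")
  codes <- peptide_code_matrix(peptides, config)
  ab <- peptide_alphabet(config$pad_char)
  m <- vapply(seq_len(ncol(codes)), function(j)
    tabulate(codes[, j], nbins = 21L), integer(21L))
  m <- m / length(peptides)
  dimnames(m) <- list(ab, window_positions(config))
  attr(m, "n") <- length(peptides)
  class(m) <- c("position_frequency_matrix", class(m))
  m
}

#' Two-sample positional residue enrichment
#'
#' For every (position, residue) pair, the per-peptide 0/1 occurrence
#' indicators of the two sets are compared with a Welch two-sample t-test;
#' pairs with `p < alpha` are reported, signed by the frequency difference
#' (`enriched` = more frequent in `positives`). When both sets are constant
#' with equal frequency the pair is not reported; when both are constant
#' but different the difference is certain and reported with p = 0.
#'
#' @param positives,negatives Character vectors of equal-length windows (or
#'   data frames with a `peptide` column).
#' @param alpha Significance level, default 0.05.
#' @param correction Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (matching common two-sample logo
#'   practice).
#' @param config A [window_config()].
#' @return Data frame with `position`, `residue`, `direction`, `statistic`,
#'   `p_value`, `freq_positive`, `freq_negative`, sorted by p-value.
#' @export
two_sample_enrichment <- function(positives, negatives, alpha = 0.05,
                                  correction = "none",
                                  config = window_config()) {
  if (is.data.frame(positives)) positives <- positives$peptide
  if (is.data.frame(negatives)) negatives <- negatives$peptide
  if (!length(positives) || !length(negatives))
    stop("both peptide sets must be non-empty")
  cp <- peptide_code_matrix(positives, config)
  cn <- peptide_code_matrix(negatives, config)
  n1 <- nrow(cp); n2 <- nrow(cn)
  ab <- peptide_alphabet(config$pad_char)
  pos_lab <- window_positions(config)
  res <- list()
  for (j in seq_len(config$length)) {
    f1 <- tabulate(cp[, j], nbins = 21L) / n1
    f2 <- tabulate(cn[, j], nbins = 21L) / n2
    # Welch t on Bernoulli indicators, in closed form (sample variances)
    v1 <- f1 * (1 - f1) * n1 / max(n1 - 1L, 1L)
    v2 <- f2 * (1 - f2) * n2 / max(n2 - 1L, 1L)
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, (f1 - f2) / sqrt(se2),
                    ifelse(f1 == f2, 0, Inf * sign(f1 - f2)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / max(n1 - 1L, 1L) +
                          (v2 / n2)^2 / max(n2 - 1L, 1L)),
                 NA_real_)
    pval <- ifelse(is.finite(tstat) & !is.na(df),
                   2 * pt(-abs(tstat), df),
                   ifelse(f1 == f2, 1, 0))
    res[[j]] <- data.frame(position = pos_lab[j], residue = ab,
                           statistic = tstat, p_value = pval,
                           freq_positive = f1, freq_negative = f2,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = correction)
  out <- out[out$p_value < alpha & out$freq_positive != out$freq_negative, ,
             drop = FALSE]
  out$direction <- ifelse(out$freq_positive > out$freq_negative,
                          "enriched", "depleted")
  out <- out[order(out$p_value), c("position", "residue", "direction",
                                   "statistic", "p_value",
                                   "freq_positive", "freq_negative")]
  rownames(out) <- NULL
  out
}
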