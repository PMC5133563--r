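# 687-dimensional feature encoding of 16-mer peptide windows.
#
# Layout (fixed and documented):
#   block A:  21 one-gram counts, residue codes 1..21
#   block B: 441 two-gram counts, lexicographic by (code1, code2)
#   block C:  15 position-specific residue codes, positions -xi..-1,+1..+eta
#   block D: 210 physicochemical values, position-major over the same 15
#            positions, 14 properties per position
# The invariant center lysine carries no information and is excluded from
# blocks C and D.

#' Names of the 687 encoded features
#'
#' @param config A [window_config()].
#' @param table A `property_table` (names its 14 columns).
#' @return Character vector, e.g. `g1_A`, `g2_AK`, `pos_-3_code`,
#'   `pc_+2_polarity`.
#' @export
feature_names <- function(config = window_config(),
                          table = default_property_table()) {
  ab <- peptide_alphabet(config$pad_char)
  pos <- window_positions(config, drop_center = TRUE)
  props <- colnames(table)
  c(paste0("g1_", ab),
    paste0("g2_", rep(ab, each = 21L), rep(ab, times = 21L)),
    paste0("pos_", pos, "_code"),
    paste0("pc_", rep(pos, each = length(props)), "_",
           rep(props, times = length(pos))))
}

# Column index ranges of the four blocks.
feature_blocks <- function(config = window_config()) {
  nflank <- config$length - 1L
  list(kgram1 = 1:21,
       kgram2 = 21L + 1:441,
       position = 462L + seq_len(nflank),
       physchem = 462L + nflank + seq_len(nflank * 14L))
}

#' Encode peptide windows into the 687-dimensional feature matrix
#'
#' @param peptides Character vector of windows (all of `config$length`), or
#'   a data frame with a `peptide` column.
#' @param table A `property_table`; default [default_property_table()].
#' @param config A [window_config()].
#' @param kgram_values `"count"` (default; the k-gram spectrum counts) or
#'   `"binary"` (presence/absence).
#' @return Numeric matrix, one row per peptide, 687 named columns.
#' @export
#' @examples
#' x <- encode_peptides("AAAAAAKAAAAAAAAA")
#' x[1, "g1_A"]   # 15
#' x[1, "g2_AK"]  # 1
encode_peptides <- function(peptides, table = default_property_table(),
                            config = window_config(),
                            kgram_values = c("count", "binary")) {
  kgram_values <- match.arg(kgram_values)
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  codes <- peptide_code_matrix(peptides, config)
  n <- nrow(codes); L <- config$length
  # block A: per-row residue counts
  A <- matrix(0, n, 21L)
  for (a in 1:21) A[, a] <- rowSums(codes == a)
  # block B: counts over the L-1 overlapping adjacent pairs
  pair <- (codes[, -L, drop = FALSE] - 1L) * 21L + codes[, -1L, drop = FALSE]
  B <- matrix(0, n, 441L)
  for (j in seq_len(L - 1L)) {
    idx <- cbind(seq_len(n), pair[, j])
    B[idx] <- B[idx] + 1
  }
  if (kgram_values == "binary") {
    A <- (A > 0) + 0
    B <- (B > 0) + 0
  }
  # block C: ordinal residue codes at the 15 non-center positions
  flank <- c(seq_len(config$xi), config$xi + 1L + seq_len(config$eta))
  C <- codes[, flank, drop = FALSE]
  # block D: 14 property values per flank position (dummy residue -> 0)
  pm <- rbind(unclass(table), X = rep(0, ncol(table)))
  D <- matrix(0, n, ncol(C) * 14L)
  for (j in seq_len(ncol(C)))
    D[, (j - 1L) * 14L + 1:14] <- pm[C[, j], , drop = FALSE]
  out <- cbind(A, B, C, D)
  colnames(out) <- feature_names(config, table)
  rownames(out) <- NULL
  out
}

#' Encode a single peptide window
#'
#' Convenience wrapper around [encode_peptides()]; the encoding is a pure
#' function of the window string.
#'
#' @inheritParams encode_peptides
#' @param peptide A single window string.
#' @return Named numeric vector of length 687.
#' @export
encode_peptide <- function(peptide, table = default_property_table(),
                           config = window_config(),
                           kgram_values = c("count", "binary")) {
  stopifnot(length(peptide) == 1L)
  encode_peptides(peptide, table, config, kgram_values)[1L, ]
}

#' Basic k-gram block (k = 1, 2) of a window
#' @inheritParams encode_peptide
#' @return Named numeric vector of length 462 (21 one-gram counts followed
#'   by 441 two-gram counts).
#' @export
encode_basic_kgrams <- function(peptide, config = window_config(),
                                kgram_values = c("count", "binary")) {
  v <- encode_peptide(peptide, config = config, kgram_values = kgram_values)
  v[unlist(feature_blocks(config)[c("kgram1", "kgram2")])]
}

#' Position-specific residue-code block of a window
#' @inheritParams encode_peptide
#' @return Named integer-valued vector of length 15: the numeric residue
#'   codes at positions `-xi..-1, +1..+eta` (the invariant center lysine is
#'   excluded).
#' @export
encode_position_codes <- function(peptide, config = window_config()) {
  v <- encode_peptide(peptide, config = config)
  v[feature_blocks(config)$position]
}

#' Physicochemical block of a window
#' @inheritParams encode_peptide
#' @return Named numeric vector of length 210: for each of the 15 flank
#'   positions, the residue's 14 property values (dummy residue
#'   contributes 0 throughout).
#' @export
encode_physicochemical <- function(peptide, table = default_property_table(),
                                   config = window_config()) {
  v <- encode_peptide(peptide, table = table, config = config)
  v[feature_blocks(config)$physchem]
}

#' Fit a constant-feature reduction mask
#'
#' Features that take a single value across all rows (both classes pooled)
#' carry no information for any classifier and are dropped; the fitted mask
#' records which columns survive.
#'
#' @param x Numeric feature matrix (>= 2 rows).
#' @return An object of class `reduction_mask` with elements `keep`
#'   (named logical), `n_kept`, `n_removed`.
#' @export
fit_reduction_mask <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L)
    stop("fit_reduction_mask requires a matrix with at least 2 rows")
  rng <- apply(x, 2L, function(col) max(col) - min(col))
  keep <- rng > 0
  structure(list(keep = keep, n_kept = sum(keep), n_removed = sum(!keep),
                 n_features = length(keep)),
            class = "reduction_mask")
}

#' @export
print.reduction_mask <- function(x, ...) {
  cat(sprintf("reduction_mask: %d of %d features kept (%d constant removed)\n",
              x$n_kept, x$n_features, x$n_removed))
  invisible(x)
}

#' Apply a reduction mask
#'
#' Order-preserving projection onto the kept features.
#'
#' @param x Numeric vector or matrix with as many features as the mask.
#' @param mask A `reduction_mask` from [fit_reduction_mask()].
#' @return The reduced vector or matrix.
#' @export
apply_reduction <- function(x, mask) {
  stopifnot(inherits(mask, "reduction_mask"))
  if (is.matrix(x)) {
    if (ncol(x) != mask$n_features)
      stop(sprintf("matrix has %d columns; mask expects %d",
                   ncol(x), mask$n_features))
    x[, mask$keep, drop = FALSE]
  } else {
    if (length(x) != mask$n_features)
      stop(sprintf("vector has length %d; mask expects %d",
                   length(x), mask$n_features))
    x[mask$keep]
  }
}
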