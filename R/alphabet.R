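# Residue alphabet and coding shared by the whole package.

#' The 20 native amino acids, alphabetical by one-letter code
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The 21-symbol peptide alphabet (20 amino acids plus the dummy residue)
#'
#' The dummy residue `X` marks positions beyond a protein terminus and
#' substituted unknown residues.
#'
#' @param pad_char Dummy residue symbol, default `"X"`.
#' @return Character vector of length 21.
#' @export
peptide_alphabet <- function(pad_char = "X") {
  c(amino_acids(), pad_char)
}

#' Numeric residue codes
#'
#' The 20 native amino acids are numbered 1--20 in alphabetical order of
#' their one-letter codes (A = 1, C = 2, ..., Y = 20); the dummy residue is
#' code 21.
#'
#' @param pad_char Dummy residue symbol, default `"X"`.
#' @return Named integer vector mapping residue to code.
#' @export
#' @examples
#' residue_codes()[c("A", "K", "X")]  # 1, 9, 21
residue_codes <- function(pad_char = "X") {
  setNames(seq_len(21L), peptide_alphabet(pad_char))
}

# Residues that may occur in real sequence data but are outside the fixed
# 21-symbol encoding alphabet; mapped to the dummy residue with a warning.
.nonstandard_residues <- c("B", "J", "O", "U", "Z", "*")

#' Window geometry for lysine-centered peptide extraction
#'
#' A window covers `xi` residues upstream of the candidate lysine, the
#' lysine itself, and `eta` residues downstream, for a total length of
#' `xi + 1 + eta`. The defaults (`xi = 6`, `eta = 9`) give the 16-mer used
#' throughout the package; they reflect the asymmetric coverage of the
#' peptides the benchmark data derive from.
#'
#' @param xi Upstream flank length (non-negative integer), default 6.
#' @param eta Downstream flank length (non-negative integer), default 9.
#' @param pad_char Dummy residue used to fill positions that fall outside
#'   the protein, default `"X"`.
#' @return An object of class `window_config`.
#' @export
window_config <- function(xi = 6L, eta = 9L, pad_char = "X") {
  xi <- as.integer(xi)
  eta <- as.integer(eta)
  stopifnot(length(xi) == 1L, length(eta) == 1L, xi >= 0L, eta >= 0L,
            is.character(pad_char), nchar(pad_char) == 1L)
  if (pad_char %in% amino_acids())
    stop("pad_char must not be one of the 20 amino acid codes")
  structure(
    list(xi = xi, eta = eta, pad_char = pad_char, length = xi + 1L + eta),
    class = "window_config"
  )
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("window_config: xi = %d, eta = %d, length = %d, pad = '%s'\n",
              x$xi, x$eta, x$length, x$pad_char))
  invisible(x)
}

#' Position labels of a window
#'
#' @param config A [window_config()].
#' @param drop_center Drop the (invariant) center position? Default `FALSE`.
#' @return Character labels `-xi ... -1, 0, +1 ... +eta` (center `"0"`).
#' @export
window_positions <- function(config = window_config(), drop_center = FALSE) {
  lab <- c(paste0("-", rev(seq_len(config$xi))), "0",
           paste0("+", seq_len(config$eta)))
  if (drop_center) lab <- lab[lab != "0"]
  lab
}

# Convert peptides (equal-length strings) to an integer code matrix.
# Non-alphabet symbols are mapped to the dummy code with a single warning.
peptide_code_matrix <- function(peptides, config = window_config()) {
  stopifnot(is.character(peptides), length(peptides) > 0L)
  L <- config$length
  if (any(nchar(peptides) != L))
    stop(sprintf("all peptides must have length %d", L))
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), ncol = L, byrow = TRUE)
  codes <- residue_codes(config$pad_char)
  m <- matrix(codes[chars], nrow = nrow(chars), ncol = L)
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    warning(sprintf("non-alphabet residue(s) %s mapped to '%s'",
                    paste(sQuote(bad), collapse = ", "), config$pad_char))
    m[is.na(m)] <- 21L
  }
  m
}
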