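# FASTA / site-table / peptide-table I/O and window extraction.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and returned in file order. Record ids are the
#' first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("failed to parse FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (length(seqs) == 0L) return(setNames(character(0), character(0)))
  if (any(!nzchar(ids)))
    stop(sprintf("record %d in '%s' has an empty header", which(!nzchar(ids))[1], path))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop(sprintf("empty sequence for record '%s' in '%s'", ids[empty][1], path))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate record id(s) in '%s': %s",
                 path, paste(unique(dup), collapse = ", ")))
  setNames(seqs, ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Expects a headered TSV with columns `protein_id`, `position` (1-based)
#' and `label`. Labels may be `1`/`0` or `positive`/`negative`.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `protein_id` (character), `position`
#'   (integer) and `label` (integer 0/1).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("site table not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("site table '%s' lacks column(s): %s",
                 path, paste(miss, collapse = ", ")))
  data.frame(protein_id = as.character(df$protein_id),
             position = as.integer(df$position),
             label = normalize_labels(df$label),
             stringsAsFactors = FALSE)
}

#' Write a site-annotation table
#' @param sites Data frame with `protein_id`, `position`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  write_tsv(sites[, c("protein_id", "position", "label")], path)
}

#' Read a labeled peptide table
#'
#' Expects a headered TSV with columns `peptide` and `label` (optionally
#' also `protein_id` and `position`), one fixed-length window per row.
#'
#' @param path Path to the TSV.
#' @return Data frame with at least `peptide` (character) and `label`
#'   (integer 0/1).
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("peptide table not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "label") %in% names(df)))
    stop(sprintf("peptide table '%s' must have columns 'peptide' and 'label'", path))
  df$peptide <- toupper(as.character(df$peptide))
  df$label <- normalize_labels(df$label)
  df
}

#' Write a labeled peptide table
#' @param peptides Data frame with at least `peptide` and `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  keep <- intersect(c("protein_id", "position", "peptide", "label"),
                    names(peptides))
  write_tsv(peptides[, keep, drop = FALSE], path)
}

# Headered, tab-delimited, newline-terminated TSV used for all tabular output.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

normalize_labels <- function(label) {
  if (is.numeric(label)) {
    lab <- as.integer(label)
  } else {
    x <- tolower(trimws(as.character(label)))
    lab <- ifelse(x %in% c("1", "positive", "pos", "true"), 1L,
                  ifelse(x %in% c("0", "negative", "neg", "false"), 0L, NA_integer_))
  }
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("labels must be 1/0 or positive/negative")
  lab
}

#' Extract a lysine-centered peptide window
#'
#' Returns the `xi + 1 + eta` residues centered at `position`; positions
#' that fall outside the protein are filled with the dummy residue.
#' Residues outside the 21-symbol alphabet (`B`, `J`, `O`, `U`, `Z`, `*`,
#' ...) are substituted by the dummy residue with a warning.
#'
#' @param sequence Protein sequence (character scalar).
#' @param position 1-based residue position; the residue there is expected
#'   to be `K` for benchmark windows.
#' @param config A [window_config()].
#' @param center_check `"error"` (default), `"warn"` or `"none"`: what to do
#'   when the residue at `position` is not lysine.
#' @return Character scalar of length `config$length`.
#' @export
#' @examples
#' extract_window("MKAA", 2)  # "XXXXXMKAAXXXXXXX"
extract_window <- function(sequence, position, config = window_config(),
                           center_check = c("error", "warn", "none")) {
  center_check <- match.arg(center_check)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > n)
    stop(sprintf("position %d out of range [1, %d]", position, n))
  center <- substr(sequence, position, position)
  if (center != "K" && center_check != "none") {
    msg <- sprintf("residue at position %d is '%s', not K", position, center)
    if (center_check == "error") stop(msg) else warning(msg)
  }
  idx <- (position - config$xi):(position + config$eta)
  chars <- rep(config$pad_char, length(idx))
  inside <- idx >= 1L & idx <= n
  chars[inside] <- substring(sequence, idx[inside], idx[inside])
  bad <- !(chars %in% peptide_alphabet(config$pad_char))
  if (any(bad)) {
    warning(sprintf("non-alphabet residue(s) %s mapped to '%s'",
                    paste(sQuote(unique(chars[bad])), collapse = ", "),
                    config$pad_char))
    chars[bad] <- config$pad_char
  }
  paste(chars, collapse = "")
}

#' Build a labeled benchmark of lysine-centered windows
#'
#' One window is extracted per annotated site. When `negatives = "auto"`
#' and the annotation table contains no negative rows, every non-annotated
#' lysine of the annotated proteins becomes a negative site; with
#' `negatives = "given"` only the listed sites are used.
#'
#' @param proteins Named character vector of sequences (see [read_fasta()]).
#' @param sites Data frame with `protein_id`, `position`, `label`
#'   (see [read_site_table()]).
#' @param config A [window_config()].
#' @param negatives `"auto"` (default) or `"given"`.
#' @return Data frame with columns `protein_id`, `position`, `peptide`,
#'   `label`, positives first within each protein ordering preserved.
#' @export
build_benchmark <- function(proteins, sites, config = window_config(),
                            negatives = c("auto", "given")) {
  negatives <- match.arg(negatives)
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  sites$label <- normalize_labels(sites$label)
  unknown <- setdiff(unique(sites$protein_id), names(proteins))
  if (length(unknown))
    stop(sprintf("annotations refer to unknown protein(s): %s",
                 paste(unknown, collapse = ", ")))
  # Every annotated site must sit on a lysine.
  center <- substring(proteins[sites$protein_id], sites$position, sites$position)
  off <- which(center != "K")
  if (length(off))
    stop(sprintf("annotation(s) not on a K residue: %s",
                 paste(sprintf("%s:%d(%s)", sites$protein_id[off],
                               sites$position[off], center[off]),
                       collapse = ", ")))
  if (negatives == "auto" && !any(sites$label == 0L)) {
    auto <- do.call(rbind, lapply(unique(sites$protein_id), function(id) {
      kpos <- k_positions(proteins[[id]])
      annotated <- sites$position[sites$protein_id == id]
      neg <- setdiff(kpos, annotated)
      if (!length(neg)) return(NULL)
      data.frame(protein_id = id, position = neg, label = 0L,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(auto)) sites <- rbind(sites, auto)
  }
  if (nrow(sites) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      peptide = character(0), label = integer(0),
                      stringsAsFactors = FALSE))
  peptide <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(proteins[[sites$protein_id[i]]], sites$position[i],
                   config, center_check = "none")
  }, character(1))
  out <- data.frame(protein_id = sites$protein_id, position = sites$position,
                    peptide = peptide, label = sites$label,
                    stringsAsFactors = FALSE)
  out[order(-out$label, match(out$protein_id, names(proteins)), out$position), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

k_positions <- function(sequence) {
  which(strsplit(sequence, "", fixed = TRUE)[[1]] == "K")
}

#' Greedy redundancy filter on equal-length peptide windows
#'
#' Pairwise identity is the fraction of positions with exactly matching
#' residues (Hamming identity on ungapped equal-length windows; the dummy
#' residue counts as an ordinary symbol). The filter makes a single greedy
#' pass in input order: a window is removed when its identity to any
#' previously *retained* window is `>= threshold`. Retained windows are
#' therefore mutually below the threshold, and re-filtering a filtered set
#' removes nothing.
#'
#' @param peptides Character vector of equal-length windows, or a data
#'   frame with a `peptide` column (rows are then filtered).
#' @param threshold Identity threshold in (0, 1], default 0.4.
#' @param scope `"all"` (default; compare against all retained windows) or
#'   `"within-class"` (compare only within the same label; requires labels).
#' @param labels Optional integer 0/1 labels (taken from the data frame's
#'   `label` column when present).
#' @return The retained windows (same type as input) with attribute
#'   `removal_log`: a data frame of removed windows, their closest retained
#'   match and the identity to it.
#' @export
redundancy_filter <- function(peptides, threshold = 0.4,
                              scope = c("all", "within-class"), labels = NULL) {
  scope <- match.arg(scope)
  df <- NULL
  if (is.data.frame(peptides)) {
    df <- peptides
    if (is.null(labels) && "label" %in% names(df)) labels <- df$label
    peptides <- df$peptide
  }
  stopifnot(is.character(peptides), length(peptides) > 0L,
            threshold > 0, threshold <= 1)
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("all windows must have the same length")
  if (scope == "within-class" && is.null(labels))
    stop("scope = 'within-class' requires labels")
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), ncol = L, byrow = TRUE)
  keep <- logical(length(peptides))
  removed <- integer(0); matched <- integer(0); ident <- numeric(0)
  for (i in seq_along(peptides)) {
    pool <- which(keep)
    if (scope == "within-class" && length(pool))
      pool <- pool[labels[pool] == labels[i]]
    if (length(pool)) {
      m <- chars[pool, , drop = FALSE] ==
        matrix(chars[i, ], nrow = length(pool), ncol = L, byrow = TRUE)
      id <- rowSums(m) / L
      j <- which.max(id)
      if (id[j] >= threshold) {
        removed <- c(removed, i); matched <- c(matched, pool[j])
        ident <- c(ident, id[j])
        next
      }
    }
    keep[i] <- TRUE
  }
  log <- data.frame(removed_index = removed,
                    removed_peptide = peptides[removed],
                    matched_index = matched,
                    matched_peptide = peptides[matched],
                    identity = ident,
                    stringsAsFactors = FALSE)
  out <- if (is.null(df)) peptides[keep] else {
    r <- df[keep, , drop = FALSE]; rownames(r) <- NULL; r
  }
  attr(out, "removal_log") <- log
  out
}

#' Pairwise Hamming identity of two equal-length windows
#' @param a,b Character scalars of equal length.
#' @return Fraction of matching positions.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}
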