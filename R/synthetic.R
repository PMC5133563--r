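# Synthetic benchmark generator: labeled 16-mers with controllable
# positional signal, and whole proteomes that round-trip through window
# extraction.

#' Specification of a synthetic benchmark
#'
#' The defaults emulate the published benchmark's study conditions: 458
#' positive and 3,974 negative 16-mers (about 1:8.7 imbalance), a uniform
#' background over the 20 amino acids, glycine planted at positions -3, -1
#' and +2 of positives, lysine planted at +1, +2 and +8 of negatives, and a
#' small fraction of windows truncated at a protein terminus (dummy-residue
#' padding).
#'
#' @param n_positive,n_negative Class sizes, defaults 458 and 3974.
#' @param background Named numeric vector of residue probabilities over the
#'   20 amino acids (normalized internally); default uniform.
#' @param positive_rules,negative_rules Data frames with columns `position`
#'   (integer in `-xi..eta`, nonzero), `residue`, `prob`: at each listed
#'   position the residue overrides the background draw with the given
#'   probability, in the respective class.
#' @param padding_fraction Fraction of windows whose upstream or downstream
#'   terminus is replaced by a run of dummy residues (emulating sites near
#'   protein ends), default 0.05.
#' @param window A [window_config()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 458L, n_negative = 3974L,
                           background = NULL,
                           positive_rules = data.frame(
                             position = c(-3L, -1L, 2L), residue = "G",
                             prob = 0.3),
                           negative_rules = data.frame(
                             position = c(1L, 2L, 8L), residue = "K",
                             prob = 0.25),
                           padding_fraction = 0.05,
                           window = window_config()) {
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20L), amino_acids())
  background <- background[amino_acids()] / sum(background)
  check_rules <- function(rules) {
    if (is.null(rules) || !nrow(rules)) return(invisible())
    stopifnot(all(c("position", "residue", "prob") %in% names(rules)),
              all(rules$prob >= 0 & rules$prob <= 1),
              all(rules$residue %in% amino_acids()))
    if (any(rules$position == 0L) ||
        any(rules$position < -window$xi) || any(rules$position > window$eta))
      stop(sprintf("rule positions must be in -%d..%d excluding 0",
                   window$xi, window$eta))
  }
  check_rules(positive_rules); check_rules(negative_rules)
  stopifnot(n_positive >= 0L, n_negative >= 0L,
            padding_fraction >= 0, padding_fraction <= 1)
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 background = background,
                 positive_rules = positive_rules,
                 negative_rules = negative_rules,
                 padding_fraction = padding_fraction,
                 window = window),
            class = "synthetic_spec")
}

# Window-string column index of a signed position.
rule_column <- function(position, window) {
  ifelse(position < 0L, window$xi + 1L + position, window$xi + 1L + position)
}

# Draw n flank-residue matrices from the background and apply enrichment
# rules; returns full window strings with the center K inserted.
draw_windows <- function(n, rules, spec) {
  w <- spec$window
  if (n == 0L) return(character(0))
  chars <- matrix(sample(amino_acids(), n * (w$length - 1L), replace = TRUE,
                         prob = spec$background),
                  nrow = n)
  # flank columns 1..xi map to window columns 1..xi; columns xi+1..xi+eta
  # map to window columns xi+2..L
  full <- matrix("", n, w$length)
  full[, seq_len(w$xi)] <- chars[, seq_len(w$xi)]
  full[, w$xi + 1L] <- "K"
  full[, w$xi + 1L + seq_len(w$eta)] <- chars[, w$xi + seq_len(w$eta)]
  if (!is.null(rules) && nrow(rules)) {
    for (i in seq_len(nrow(rules))) {
      col <- rule_column(rules$position[i], w)
      hit <- runif(n) < rules$prob[i]
      full[hit, col] <- rules$residue[i]
    }
  }
  if (spec$padding_fraction > 0) {
    pad <- runif(n) < spec$padding_fraction
    for (i in which(pad)) {
      if (runif(1) < 0.5) {
        len <- sample.int(w$xi, 1L)
        full[i, seq_len(len)] <- w$pad_char
      } else {
        len <- sample.int(w$eta, 1L)
        full[i, w$length - seq_len(len) + 1L] <- w$pad_char
      }
    }
  }
  apply(full, 1L, paste, collapse = "")
}

#' Generate a labeled synthetic peptide dataset
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed; regeneration from the same spec and seed is
#'   identical.
#' @return Data frame with `peptide` and `label` columns (positives first)
#'   and the generating spec in attribute `spec`.
#' @export
generate_windows <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pos <- draw_windows(spec$n_positive, spec$positive_rules, spec)
  neg <- draw_windows(spec$n_negative, spec$negative_rules, spec)
  out <- data.frame(peptide = c(pos, neg),
                    label = rep(c(1L, 0L), c(length(pos), length(neg))),
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate a synthetic proteome with annotated lysine sites
#'
#' Builds random proteins by splicing spec-generated 16-mer windows
#' (without terminal padding) between short spacer segments, so that
#' [extract_window()] at each annotated position recovers exactly the
#' planted window. A fraction of proteins is truncated to fewer than 16
#' residues around a single site, forcing dummy-residue padding on
#' extraction.
#'
#' @param n_proteins Number of proteins, default 50.
#' @param sites_per_protein Mean number of candidate lysine sites per
#'   protein (Poisson, at least 1), default 5.
#' @param site_density Probability that a planted site is positive; default
#'   the class ratio of `spec` (458 / 4432). `0` yields a site table with
#'   no positives.
#' @param spec A [synthetic_spec()] describing the window composition.
#' @param short_protein_fraction Fraction of proteins truncated below the
#'   window length, default 0.1.
#' @param seed RNG seed.
#' @return List with `proteins` (named character vector), `sites` (data
#'   frame `protein_id`, `position`, `label`) and `windows` (the expected
#'   extracted 16-mers, aligned with `sites`).
#' @export
generate_proteome <- function(n_proteins = 50L, sites_per_protein = 5,
                              site_density = NULL,
                              spec = synthetic_spec(),
                              short_protein_fraction = 0.1,
                              seed = 1L) {
  stopifnot(n_proteins >= 1L, sites_per_protein >= 1)
  if (is.null(site_density))
    site_density <- spec$n_positive / max(spec$n_positive + spec$n_negative, 1L)
  stopifnot(site_density >= 0, site_density <= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  w <- spec$window
  nopad <- spec; nopad$padding_fraction <- 0
  spacer_pool <- setdiff(amino_acids(), "K")
  proteins <- character(n_proteins)
  names(proteins) <- sprintf("SYN%04d", seq_len(n_proteins))
  sites <- list(); windows <- list()
  for (p in seq_len(n_proteins)) {
    short <- runif(1) < short_protein_fraction
    m <- if (short) 1L else max(1L, rpois(1L, sites_per_protein))
    lab <- as.integer(runif(m) < site_density)
    win <- vapply(seq_len(m), function(i)
      draw_windows(1L, if (lab[i] == 1L) spec$positive_rules
                       else spec$negative_rules, nopad),
      character(1))
    seq_parts <- character(0); centers <- integer(m); len <- 0L
    for (i in seq_len(m)) {
      spacer <- if (short) "" else
        paste(sample(spacer_pool, sample(0:5, 1L), replace = TRUE),
              collapse = "")
      seq_parts <- c(seq_parts, spacer, win[i])
      centers[i] <- len + nchar(spacer) + w$xi + 1L
      len <- len + nchar(spacer) + w$length
    }
    protein <- paste(seq_parts, collapse = "")
    expected <- win
    if (short) {
      # truncate the single window at one terminus -> padding on extraction
      cut <- sample.int(w$xi, 1L)
      protein <- substr(protein, cut + 1L, nchar(protein))
      centers[1L] <- centers[1L] - cut
      expected <- paste0(strrep(w$pad_char, cut),
                         substr(win[1L], cut + 1L, w$length))
    }
    proteins[p] <- protein
    sites[[p]] <- data.frame(protein_id = names(proteins)[p],
                             position = centers, label = lab,
                             stringsAsFactors = FALSE)
    windows[[p]] <- expected
  }
  list(proteins = proteins,
       sites = do.call(rbind, sites),
       windows = unlist(windows))
}
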