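# Independent reference implementations used as oracles, plus small
# fixture builders. These deliberately share no code with the package.

# Plug-in mutual information via table(), in nats.
naive_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
    }
  }
  unname(s)
}

# Naive greedy mRMR: recomputes every pairwise MI from scratch each step.
# Operates on an already-discrete integer matrix.
naive_mrmr <- function(X, y, n, scheme = "MID") {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) naive_mi(X[, j], y), numeric(1))
  sel <- integer(0)
  for (t in seq_len(n)) {
    cand <- setdiff(seq_len(p), sel)
    score <- vapply(cand, function(f) {
      if (!length(sel)) return(rel[f])
      red <- mean(vapply(sel, function(s) naive_mi(X[, f], X[, s]), numeric(1)))
      if (scheme == "MID") rel[f] - red
      else rel[f] / max(red, .Machine$double.eps)
    }, numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# Random 16-mers over the full 21-letter alphabet.
random_windows <- function(n, seed = 1, alphabet = peptide_alphabet()) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, 16, replace = TRUE), collapse = ""),
         character(1))
}

# A fast pipeline for tests that exercise the chain, not its accuracy.
tiny_pipeline <- function(n_features = 5L) {
  mal_pipeline(n_features = n_features)
}

# Small strongly-separated labeled set: positives are glycine-rich,
# negatives alanine-rich, center K everywhere.
toy_separable <- function(n_per_class = 15L, seed = 42) {
  set.seed(seed)
  mk <- function(res) {
    vapply(seq_len(n_per_class), function(i) {
      flank <- ifelse(runif(15) < 0.75, res,
                      sample(amino_acids(), 15, replace = TRUE))
      paste0(paste(flank[1:6], collapse = ""), "K",
             paste(flank[7:15], collapse = ""))
    }, character(1))
  }
  data.frame(peptide = c(mk("G"), mk("A")),
             label = rep(c(1L, 0L), each = n_per_class),
             stringsAsFactors = FALSE)
}
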