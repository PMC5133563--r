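test_that("FASTA parsing preserves order, uppercases, and validates records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "mkaa", ">P2", "GGGK", "AAAA"), f)
  prot <- read_fasta(f)
  expect_identical(prot, c(P1 = "MKAA", P2 = "GGGKAAAA"))

  writeLines(character(0), f)
  expect_length(read_fasta(f), 0L)

  writeLines(c(">P1", "MKAA", ">P1", "GGGG"), f)
  expect_error(read_fasta(f), "P1")

  expect_error(read_fasta(file.path(tempdir(), "no-such.fasta")), "not found")
})

test_that("FASTA round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(A1 = "MKAAGGGKRRR", B2 = strrep("ACDK", 30))
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("extract_window pads termini and has constant length", {
  expect_identical(extract_window("MKAA", 2), "XXXXXMKAAXXXXXXX")
  # interior site with full flanks contains no padding
  prot <- strrep("A", 30)
  prot <- paste0(substr(prot, 1, 14), "K", substr(prot, 16, 30))
  w <- extract_window(prot, 15)
  expect_false(grepl("X", w))
  expect_identical(nchar(w), 16L)
  # total over all positions of several proteins
  for (p in c("KAAK", "MKAAGGGKRRRKAAK", strrep("K", 20))) {
    for (pos in seq_len(nchar(p))) {
      expect_identical(
        nchar(extract_window(p, pos, center_check = "none")), 16L)
    }
  }
  expect_error(extract_window("MKAA", 0), "out of range")
  expect_error(extract_window("MKAA", 5), "out of range")
  expect_error(extract_window("MKAA", 1), "not K")
  expect_warning(extract_window("MKAA", 3, center_check = "warn"), "not K")
})

test_that("non-standard residues are substituted by the dummy with a warning", {
  expect_warning(w <- extract_window("MKUB", 2), "mapped to 'X'")
  expect_identical(substr(w, 8, 9), "XX")
})

test_that("build_benchmark auto-generates negatives from non-annotated lysines", {
  prot <- c(P1 = "AKAKAKA")
  sites <- data.frame(protein_id = "P1", position = 2L, label = 1L)
  bench <- build_benchmark(prot, sites)
  expect_identical(sum(bench$label == 1L), 1L)
  expect_identical(sum(bench$label == 0L), 2L)
  expect_setequal(bench$position[bench$label == 0L], c(4L, 6L))
  # every peptide has K at the center
  expect_true(all(substr(bench$peptide, 7, 7) == "K"))
  # positives + negatives = number of K residues in annotated proteins
  expect_identical(nrow(bench), length(k_positions <- gregexpr("K", "AKAKAKA")[[1]]))
})

test_that("build_benchmark handles degenerate inputs and bad annotations", {
  empty <- build_benchmark(c(P1 = "AAAA"),
                           data.frame(protein_id = character(0),
                                      position = integer(0),
                                      label = integer(0)))
  expect_identical(nrow(empty), 0L)

  expect_error(
    build_benchmark(c(P1 = "AKAA"),
                    data.frame(protein_id = "P1", position = 3L, label = 1L)),
    "not on a K")
  expect_error(
    build_benchmark(c(P1 = "AKAA"),
                    data.frame(protein_id = "P9", position = 2L, label = 1L)),
    "P9")
})

test_that("build_benchmark respects given negatives", {
  prot <- c(P1 = "AKAKAKA")
  sites <- data.frame(protein_id = "P1", position = c(2L, 4L),
                      label = c(1L, 0L))
  bench <- build_benchmark(prot, sites, negatives = "given")
  expect_identical(nrow(bench), 2L)
})

test_that("redundancy_filter applies greedy Hamming identity in input order", {
  a <- "AAAAAAKAAAAAAAAA"
  dup <- redundancy_filter(c(a, a))
  expect_identical(dup, a, ignore_attr = TRUE)
  expect_identical(attr(dup, "removal_log")$identity, 1)

  b6 <- "AAAAAACCCCCCCCCC"   # agrees with a at 6/16 = 0.375 < 0.40
  expect_identical(pairwise_identity(a, b6), 6 / 16)
  expect_length(redundancy_filter(c(a, b6)), 2L)

  b7 <- "AAAAAAKCCCCCCCCC"   # 7/16 = 0.4375 >= 0.40
  expect_identical(pairwise_identity(a, b7), 7 / 16)
  kept <- redundancy_filter(c(a, b7))
  expect_identical(kept, a, ignore_attr = TRUE)
  log <- attr(kept, "removal_log")
  expect_identical(log$removed_peptide, b7)
  expect_identical(log$matched_peptide, a)

  expect_error(redundancy_filter(c("AAA", "AAAA")), "same length")
})

test_that("redundancy_filter is idempotent and greedy semantics hold", {
  set.seed(5)
  win <- random_windows(80, seed = 5, alphabet = amino_acids()[1:4])
  once <- redundancy_filter(win, threshold = 0.5)
  twice <- redundancy_filter(as.character(once), threshold = 0.5)
  expect_identical(as.character(twice), as.character(once))
  expect_identical(nrow(attr(twice, "removal_log")), 0L)
  # every retained pair is below the threshold
  kept <- as.character(once)
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1L)) {
      expect_lt(pairwise_identity(kept[i], kept[j]), 0.5)
    }
  }
})

test_that("within-class scope only compares windows sharing a label", {
  a <- "AAAAAAKAAAAAAAAA"
  out <- redundancy_filter(c(a, a), labels = c(1L, 0L),
                           scope = "within-class")
  expect_length(out, 2L)  # identical but in different classes
})

test_that("peptide tables round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ds <- data.frame(peptide = random_windows(25, seed = 9),
                   label = rep(c(1L, 0L), c(5, 20)),
                   stringsAsFactors = FALSE)
  write_peptide_table(ds, f)
  back <- read_peptide_table(f)
  expect_identical(back$peptide, ds$peptide)
  expect_identical(back$label, ds$label)
})

test_that("site tables normalize text labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tlabel",
               "P1\t2\tpositive", "P1\t4\tnegative"), f)
  sites <- read_site_table(f)
  expect_identical(sites$label, c(1L, 0L))
  expect_error(
    {
      writeLines(c("protein_id\tposition\tlabel", "P1\t2\tmaybe"), f)
      read_site_table(f)
    },
    "labels")
})
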