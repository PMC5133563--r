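test_that("the dimensional ledger holds for arbitrary windows", {
  for (w in random_windows(15, seed = 2)) {
    expect_length(encode_basic_kgrams(w), 462L)
    expect_length(encode_position_codes(w), 15L)
    expect_length(encode_physicochemical(w), 210L)
    v <- encode_peptide(w)
    expect_length(v, 687L)
    # block sums: 16 residues, 15 adjacent pairs
    expect_identical(sum(v[1:21]), 16)
    expect_identical(sum(v[22:462]), 15)
    # k-gram blocks are non-negative integers
    kg <- v[1:462]
    expect_true(all(kg >= 0 & kg == round(kg)))
    # position codes are valid alphabet codes
    expect_true(all(v[463:477] %in% 1:21))
  }
})

test_that("k-gram counts match exhaustive counting on a homopolymer window", {
  v <- encode_peptide("AAAAAAKAAAAAAAAA")
  g1 <- v[1:21]
  expect_identical(unname(g1["g1_A"]), 15)
  expect_identical(unname(g1["g1_K"]), 1)
  expect_identical(sum(g1 != 0), 2L)
  g2 <- v[22:462]
  expect_identical(unname(g2[c("g2_AA", "g2_AK", "g2_KA")]), c(13, 1, 1))
  expect_identical(sum(g2 != 0), 3L)
})

test_that("binary k-gram option records presence instead of counts", {
  v <- encode_peptide("AAAAAAKAAAAAAAAA", kgram_values = "binary")
  expect_identical(unname(v[c("g1_A", "g1_K", "g2_AA")]), c(1, 1, 1))
  expect_true(all(v[1:462] %in% c(0, 1)))
})

test_that("position codes follow the published numeric coding", {
  allA <- encode_position_codes("AAAAAAKAAAAAAAAA")
  expect_identical(unname(allA), rep(1, 15))
  padded <- encode_position_codes("XXXXXMKAAXXXXXXX")
  expect_identical(unname(padded),
                   c(21, 21, 21, 21, 21, 11, 1, 1, 21, 21, 21, 21, 21, 21, 21))
  expect_named(padded, paste0("pos_", c(paste0("-", 6:1), paste0("+", 1:9)),
                              "_code"))
})

test_that("physicochemical block is zero for dummy flanks and ignores the center", {
  allX <- encode_physicochemical("XXXXXXKXXXXXXXXX")
  expect_identical(unname(allX), rep(0, 210))
  # windows differing only at the center share blocks C and D
  a <- "ACDEFGKGHIKLMNPQ"
  b <- "ACDEFGRGHIKLMNPQ"
  expect_identical(encode_physicochemical(a), encode_physicochemical(b))
  expect_identical(encode_position_codes(a), encode_position_codes(b))
})

test_that("encoding is a pure deterministic function of the window string", {
  w <- random_windows(1, seed = 77)
  expect_identical(encode_peptide(w), encode_peptide(w))
  expect_identical(encode_peptides(rep(w, 2))[1, ],
                   encode_peptides(rep(w, 2))[2, ])
})

test_that("property tables are validated on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tbl <- default_property_table()
  expect_identical(dim(unclass(tbl)), c(20L, 14L))
  df <- data.frame(residue = rownames(tbl), unclass(tbl)[, 1:13])
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_property_table(f), "14 property columns")
  df <- data.frame(residue = rownames(tbl)[c(1:19, 1)], unclass(tbl))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_property_table(f), "one row per amino acid")
})

test_that("a custom property table flows through the encoding", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tbl <- unclass(default_property_table())
  tbl[, 1] <- seq_len(20)  # recognizable first property
  write.table(data.frame(residue = rownames(tbl), tbl), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  custom <- read_property_table(f)
  v <- encode_physicochemical("AAAAAAKAAAAAAAAA", table = custom)
  expect_identical(unname(v[seq(1, 210, by = 14)]), rep(1, 15))
})

test_that("constant features are removed by the fitted mask", {
  set.seed(3)
  x <- cbind(const1 = rep(2, 40), v1 = rnorm(40), const2 = rep(-1, 40),
             v2 = sample(0:3, 40, TRUE))
  mask <- fit_reduction_mask(x)
  expect_identical(mask$n_removed, 2L)
  expect_identical(colnames(apply_reduction(x, mask)), c("v1", "v2"))
  # identical rows: everything is constant
  all_const <- fit_reduction_mask(matrix(1, 5, 4))
  expect_identical(all_const$n_kept, 0L)
  expect_error(fit_reduction_mask(matrix(1, 1, 4)), "at least 2 rows")
})

test_that("mask fitting is row-order invariant and reduction removes all constants", {
  x <- encode_peptides(random_windows(60, seed = 12))
  mask <- fit_reduction_mask(x)
  perm <- sample(nrow(x))
  expect_identical(fit_reduction_mask(x[perm, ])$keep, mask$keep)
  xr <- apply_reduction(x, mask)
  expect_true(all(apply(xr, 2, function(col) max(col) > min(col))))
  # vector projection agrees with matrix projection
  expect_identical(apply_reduction(x[1, ], mask), xr[1, ])
  expect_error(apply_reduction(x[, 1:10], mask), "mask expects")
  expect_error(apply_reduction(x[1, 1:10], mask), "mask expects")
})

test_that("a varying flank lysine count survives reduction", {
  wins <- c("KKKKKKKKKKKKKKKK", "AAAAAAKAAAAAAAAA", "GGGGGGKGGGGGGGGG")
  mask <- fit_reduction_mask(encode_peptides(wins))
  expect_true(mask$keep[["g1_K"]])
})
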