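# Canonical 4-mer features, window geometry, normalization and weighting.

test_that("canonical tetramer set has 136 keys with revcomp folding", {
  keys <- canonical_tetramers()
  expect_length(keys, 136L)
  expect_identical(canonical_kmer("TTTT"), "AAAA")
  expect_identical(canonical_kmer("AATT"), "AATT")  # revcomp palindrome
  # brute force: every 4-mer's canonical form is in the set, and the set is
  # exactly the distinct canonical forms of all 256 4-mers
  b <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(b, b, b, b, stringsAsFactors = FALSE), 1,
                paste, collapse = "")
  rc <- vapply(all4, function(k)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(k))), "")
  oracle <- sort(unique(pmin(all4, rc)))
  expect_identical(keys, oracle)
  expect_equal(sum(all4 == rc), 16L)  # palindromes
})

test_that("window rule handles full windows, standalone and merged tails", {
  w <- scaffold_windows(12000)
  expect_equal(unname(w[, "start"]), c(0, 5000))
  expect_equal(unname(w[, "end"]), c(5000, 12000))  # 2000-tail merged
  w2 <- scaffold_windows(12600)
  expect_equal(nrow(w2), 3L)
  expect_equal(unname(w2[3, ]), c(10000, 12600))    # 2600-tail stands alone
  expect_equal(nrow(scaffold_windows(5000)), 1L)
  expect_equal(unname(scaffold_windows(3000)[1, ]), c(0, 3000))
  expect_equal(nrow(scaffold_windows(2000)), 0L)
})

test_that("windows partition every scaffold above the minimum", {
  set.seed(3)
  for (len in sample(2500:40000, 30)) {
    w <- scaffold_windows(len)
    expect_equal(sum(w[, "end"] - w[, "start"]), len)
    expect_true(all(w[-1, "start"] == w[-nrow(w), "end"]))
    expect_true(all(w[, "end"] - w[, "start"] >= 2500))
  }
})

test_that("tetranucleotide frequencies match hand counts and are strand invariant", {
  f <- tetra_frequencies("AAAATTTT")
  expect_equal(f[["AAAA"]], 0.4)   # AAAA + TTTT = 2 of 5
  expect_equal(f[["AAAT"]], 0.4)   # AAAT + ATTT = 2 of 5
  expect_equal(f[["AATT"]], 0.2)
  expect_equal(sum(f), 1)
  expect_equal(sum(f > 0), 3L)

  set.seed(4)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(tetra_frequencies(s), tetra_frequencies(rc))
    expect_equal(sum(tetra_frequencies(s)), 1)
  }
  # 4-mers containing N are skipped
  fn <- tetra_frequencies("AAAANAAAA")
  expect_equal(fn[["AAAA"]], 1)
  expect_equal(sum(tetra_frequencies("ANNNT")), 0)  # no valid 4-mer
})

toy_features <- function(weight = 5, ab = NULL) {
  set.seed(7)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 6000,
                 replace = TRUE, prob = c(2, i, i, 2)), collapse = ""), "")
  names(seqs) <- paste0("s", 1:4)
  if (is.null(ab)) {
    ab <- matrix(c(1, 2, 4, 8, 8, 4, 2, 1), 4,
                 dimnames = list(names(seqs), c("t1", "t2")))
  }
  build_features(scaffold_set(seqs), ab, weight = weight)
}

test_that("feature normalization is a per-column z-score before weighting", {
  ft <- toy_features(weight = 5)
  unweighted <- ft$combined
  unweighted[, ft$abund_cols] <- unweighted[, ft$abund_cols] / ft$weight
  nondegenerate <- ft$sds != 1 | abs(ft$centers) > 0
  expect_true(all(abs(colMeans(unweighted)) < 1e-9))
  sds <- apply(unweighted, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-9))
})

test_that("abundance weighting is exactly linear and squares in distances", {
  ft1 <- toy_features(weight = 1)
  ft2 <- toy_features(weight = 2)
  ft5 <- toy_features(weight = 5)
  expect_equal(ft2$combined[, ft2$abund_cols],
               2 * ft1$combined[, ft1$abund_cols])
  d2 <- function(ft, cols) sum((ft$combined[1, cols] - ft$combined[2, cols])^2)
  expect_equal(d2(ft5, ft5$abund_cols), 25 * d2(ft1, ft1$abund_cols))
  expect_equal(d2(ft5, ft5$tetra_cols), d2(ft1, ft1$tetra_cols))
})

test_that("constant abundance columns zero out with a message", {
  ab <- matrix(3, 4, 2, dimnames = list(paste0("s", 1:4), c("t1", "t2")))
  expect_message(ft <- toy_features(weight = 1, ab = ab), "zero-variance")
  expect_true(all(ft$combined[, ft$abund_cols] == 0))
})

test_that("short scaffolds are excluded with a warning; missing abundance errors", {
  seqs <- c(s1 = paste(rep("ACGT", 1500), collapse = ""), s2 = "ACGTACGT")
  ab <- matrix(1:2, 2, 1, dimnames = list(c("s1", "x"), "t1"))
  expect_warning(expect_error(
    build_features(scaffold_set(seqs), ab[1, , drop = FALSE] * 0 + 1), NA),
    "s2")
  ab2 <- matrix(1, 1, 1, dimnames = list("other", "t1"))
  expect_warning(expect_error(
    build_features(scaffold_set(seqs), ab2), "s1"), "s2")
})

test_that("held-out scaffolds are projected with the training parameters", {
  ft <- toy_features(weight = 5)
  set.seed(8)
  newseq <- c(held = paste(sample(c("A", "C", "G", "T"), 6000,
                                  replace = TRUE), collapse = ""))
  ab <- matrix(c(3, 3), 1, 2, dimnames = list("held", c("t1", "t2")))
  proj <- transform_features(ft, scaffold_set(newseq), ab)
  expect_equal(ncol(proj$combined), ncol(ft$combined))
  expect_equal(nrow(proj$combined), nrow(scaffold_windows(6000)))
})
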