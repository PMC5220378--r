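# Exact local alignment, reciprocal best hits, AAI and gene partitions.

test_that("alignment of identical short peptides matches hand scoring", {
  a <- align("MKV", "MKV")
  expect_equal(a$score, 14L)  # BLOSUM62 diagonal M=5, K=5, V=4
  expect_equal(a$identity, 100)
  expect_equal(a$coverage_query, 1)
  expect_equal(a$coverage_target, 1)
  expect_equal(bit_score <- a$bit_score,
               (0.267 * 14 - log(0.041)) / log(2), tolerance = 1e-12)
  # bit score of a raw 40 alignment under the configured (lambda, K)
  expect_equal((0.267 * 40 - log(0.041)) / log(2), 20.0162, tolerance = 1e-4)
  expect_error(align("MKB", "MKV"), "illegal residue")
  expect_error(align("", "MKV"), "empty")
})

test_that("self-alignment dominates cross-alignment in raw score", {
  set.seed(40)
  seqs <- random_aa(10, c(20, 20))
  for (s in seqs[1:5]) {
    self <- align(s, s)$score
    for (t in seqs[6:10]) expect_gte(self, align(s, t)$score)
  }
})

test_that("Smith-Waterman agrees with the naive full-matrix DP oracle", {
  S <- blosum62_ref()
  set.seed(41)
  qs <- random_aa(60, c(5, 30))
  ts <- random_aa(60, c(5, 30))
  for (i in seq_along(qs)) {
    got <- align(qs[i], ts[i])$score
    expect_equal(got, naive_sw_score(qs[i], ts[i], S),
                 info = paste(qs[i], ts[i]))
  }
})

test_that("alignment statistics agree with an independent aligner", {
  set.seed(42)
  # Biostrings local pairwiseAlignment as a second, independent route
  for (i in 1:20) {
    q <- random_aa(1, c(30, 60)); t <- random_aa(1, c(30, 60))
    got <- align(q, t)
    ref <- Biostrings::pairwiseAlignment(q, t,
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 11, gapExtension = 1,
                                         type = "local")
    expect_equal(got$score, Biostrings::score(ref))
  }
})

test_that("ortholog thresholds are inclusive at the stated boundaries", {
  set.seed(43)
  pp <- simulate_proteome_pair(
    proteome_pair_config(5, target_identity = 0.8, shared_fraction = 1,
                         length_mean = 120, length_min = 100, seed = 9))
  pa <- pp$proteome_a; pb <- pp$proteome_b
  a1 <- align(pa$proteins[[1]], pb$proteins[[1]])
  # bit score exactly at the minimum passes; epsilon above it fails
  at <- scoring_config(bit_min = a1$bit_score)
  above <- scoring_config(bit_min = a1$bit_score + 1e-9)
  expect_true(names(pb$proteins)[1] ==
                best_hits(pa, pb, at)[[names(pa$proteins)[1]]])
  expect_false(names(pa$proteins)[1] %in% names(best_hits(pa, pb, above)))
  # coverage exactly at the minimum passes
  cov_at <- scoring_config(coverage_min = min(a1$coverage_query,
                                              a1$coverage_target))
  expect_true(names(pa$proteins)[1] %in% names(best_hits(pa, pb, cov_at)))
  cov_above <- scoring_config(coverage_min = min(a1$coverage_query,
                                                 a1$coverage_target) + 1e-9)
  expect_false(names(pa$proteins)[1] %in% names(best_hits(pa, pb, cov_above)))
  # E-value boundary: E exactly at the maximum passes
  e_at <- scoring_config(evalue_max = a1$e_value)
  expect_true(names(pa$proteins)[1] %in% names(best_hits(pa, pb, e_at)))
  e_below <- scoring_config(evalue_max = a1$e_value * (1 - 1e-9))
  expect_false(names(pa$proteins)[1] %in% names(best_hits(pa, pb, e_below)))
})

test_that("reciprocal best hits are symmetric, one-to-one and exact on clones", {
  pp <- simulate_proteome_pair(
    proteome_pair_config(15, target_identity = 1, shared_fraction = 1,
                         seed = 10))
  tab <- rbh(pp$proteome_a, pp$proteome_b)
  expect_equal(nrow(tab$pairs), 15L)
  expect_equal(aai(tab), 100)
  expect_false(anyDuplicated(tab$pairs$id_a) > 0)
  expect_false(anyDuplicated(tab$pairs$id_b) > 0)
  # symmetry: swapping the proteome order yields the same pair set
  tab_rev <- rbh(pp$proteome_b, pp$proteome_a)
  expect_setequal(paste(tab$pairs$id_a, tab$pairs$id_b),
                  paste(tab_rev$pairs$id_b, tab_rev$pairs$id_a))
})

test_that("best hits agree with an all-vs-all brute force on toy proteomes", {
  set.seed(44)
  pa <- proteome("X", stats::setNames(random_aa(12, c(40, 70)),
                                      sprintf("X|p%02d", 1:12)))
  pb <- proteome("Y", stats::setNames(random_aa(12, c(40, 70)),
                                      sprintf("Y|p%02d", 1:12)))
  sc <- scoring_config(bit_min = 0, evalue_max = Inf, coverage_min = 0)
  bh <- best_hits(pa, pb, sc)
  for (qa in names(pa$proteins)) {
    stats_all <- lapply(pb$proteins, function(t)
      align(pa$proteins[[qa]], t, sc))
    bits <- vapply(stats_all, `[[`, numeric(1), "bit_score")
    ident <- vapply(stats_all, `[[`, numeric(1), "identity")
    best <- names(pb$proteins)[order(-bits, -ident, names(pb$proteins))[1]]
    expect_identical(unname(bh[[qa]]), best, label = qa)
  }
})

test_that("AAI recovers planted identity and errors on empty tables", {
  pp <- simulate_proteome_pair(
    proteome_pair_config(40, target_identity = 0.7, shared_fraction = 1,
                         length_mean = 220, length_min = 180, seed = 12))
  tab <- rbh(pp$proteome_a, pp$proteome_b)
  expect_lt(abs(aai(tab) - 70), 3)
  empty <- tab; empty$pairs <- tab$pairs[0, ]
  expect_error(aai(empty), "AAI undefined")
})

test_that("comparison matrices have the documented symmetry and denominators", {
  set.seed(45)
  shared <- stats::setNames(random_aa(10, c(60, 90)), sprintf("p%02d", 1:10))
  pa <- proteome("A", shared)
  pb_seqs <- c(shared, stats::setNames(random_aa(10, c(60, 90)),
                                       sprintf("q%02d", 1:10)))
  pb <- proteome("B", pb_seqs)
  cm <- compare_genomes(list(pa, pb))
  expect_equal(cm$aai["A", "B"], cm$aai["B", "A"])
  expect_true(is.na(cm$aai["A", "A"]))
  expect_equal(round(cm$aai["A", "B"]), 100)
  # A has 10 proteins all shared; B has 20, half shared
  expect_equal(cm$ortho_frac["A", "B"], 100)
  expect_equal(cm$ortho_frac["B", "A"], 50)
})

test_that("gene partition is a disjoint cover of the focal proteome", {
  pp <- simulate_proteome_pair(
    proteome_pair_config(20, target_identity = 0.9, shared_fraction = 0.4,
                         seed = 13))
  tab <- rbh(pp$proteome_a, pp$proteome_b)
  part <- gene_partition(pp$proteome_a, list(tab))
  expect_setequal(c(part$shared, part$unique), names(pp$proteome_a$proteins))
  expect_length(intersect(part$shared, part$unique), 0)
  expect_setequal(part$shared, pp$truth$id_a)

  none <- gene_partition(pp$proteome_a, list())
  expect_length(none$shared, 0)
  expect_setequal(none$unique, names(pp$proteome_a$proteins))

  other <- rbh(pp$proteome_b, pp$proteome_b)
  expect_error(gene_partition(pp$proteome_a, list(other)), "focal")
})
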