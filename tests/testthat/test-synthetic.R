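# Synthetic community and proteome generators: ground-truth recovery.

test_that("simulated genomes recover their GC targets and are seeded", {
  for (gc in c(0.30, 0.378, 0.55)) {
    g <- simulate_genome(1e5, gc, order = 3, seed = 1)
    obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
    expect_lt(abs(obs - gc), 0.01)
  }
  expect_identical(simulate_genome(1e5, 0.378, 3, seed = 1),
                   simulate_genome(1e5, 0.378, 3, seed = 1))
  expect_false(identical(simulate_genome(1e5, 0.378, 3, seed = 1),
                         simulate_genome(1e5, 0.378, 3, seed = 2)))
})

test_that("an order-0 symmetric chain emits near-uniform base frequencies", {
  g <- simulate_genome(5e4, 0.5, order = 0, seed = 7)
  freq <- table(strsplit(g, "")[[1]]) / 5e4
  expect_true(all(abs(freq[c("A", "C", "G", "T")] - 0.25) < 0.01))
})

test_that("invalid genome configurations are rejected", {
  expect_error(simulate_genome(1e5, NaN, 3, 1), "gc")
  expect_error(simulate_genome(1e5, 1.2, 3, 1), "gc")
  expect_error(simulate_genome(10000, 0.4, 3, 1), "20 kb")
})

test_that("fragmentation partitions the genome and is seeded", {
  g <- simulate_genome(1e5, 0.45, 3, seed = 3)
  fixed <- fragment_genome(g, list(mean = 10000, sigma = 0, min = 5000),
                           seed = 2, label = "genome_1")
  expect_equal(length(fixed), 10L)
  expect_identical(paste(fixed$sequences, collapse = ""), g)

  law <- list(mean = 15000, sigma = 0.45, min = 5000)
  fs1 <- fragment_genome(g, law, seed = 4)
  fs2 <- fragment_genome(g, law, seed = 4)
  expect_identical(fs1$sequences, fs2$sequences)
  expect_equal(sum(nchar(fs1$sequences)), nchar(g))
  expect_true(all(nchar(fs1$sequences) >= 5000))
  expect_error(fragment_genome(g, list(mean = 8000, sigma = 0.3, min = 4000)),
               "5000")
})

test_that("abundance is profile x scaffold-noise with correlated series", {
  com <- small_community(seed = 5)
  noiseless <- community_config(3, genome_length = 2.5e5,
                                gc_targets = c(0.32, 0.45, 0.58),
                                abundance_profiles = com$config$abundance_profiles,
                                coverage_noise_cv = 0, seed = 5)
  ab0 <- simulate_abundance(noiseless, com$scaffolds)
  labs <- com$scaffolds$labels[rownames(ab0)]
  for (g in 1:3) {
    rows <- ab0[labs == sprintf("genome_%d", g), , drop = FALSE]
    expect_true(all(apply(rows, 1, function(r)
      all(r == com$config$abundance_profiles[g, ]))))
  }
  ab <- com$abundance
  expect_true(all(ab >= 0))
  # scaffold-level noise: each scaffold's series is an exact multiple of
  # its genome profile
  sc1 <- ab[labs == "genome_1", , drop = FALSE]
  ratio <- sc1 / rep(com$config$abundance_profiles[1, ],
                     each = nrow(sc1))
  expect_true(all(abs(ratio - ratio[, 1]) < 1e-12))
})

test_that("disjoint abundance profiles give anti-correlated series", {
  profiles <- rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  cc <- community_config(2, genome_length = 1e5, gc_targets = c(0.4, 0.5),
                         abundance_profiles = profiles, seed = 8)
  sc <- simulate_community(cc)
  ab <- simulate_abundance(cc, sc)
  labs <- sc$labels[rownames(ab)]
  a <- ab[labs == "genome_1", , drop = FALSE]
  b <- ab[labs == "genome_2", , drop = FALSE]
  cors <- as.vector(cor(t(a), t(b)))
  expect_lte(mean(cors), 0)
})

test_that("unlabelled scaffolds are rejected by the abundance simulator", {
  com <- small_community()
  naked <- scaffold_set(com$scaffolds$sequences)
  expect_error(simulate_abundance(com$config, naked), "label")
})

test_that("tetranucleotide composition separates independently drawn genomes", {
  g1 <- simulate_genome(3e5, 0.42, 3, seed = 21)
  g2 <- simulate_genome(3e5, 0.42, 3, seed = 22)  # same GC, different chain
  w1 <- t(sapply(seq(1, 3e5 - 5000, by = 5000),
                 function(s) tetra_frequencies(substr(g1, s, s + 4999))))
  w2 <- t(sapply(seq(1, 3e5 - 5000, by = 5000),
                 function(s) tetra_frequencies(substr(g2, s, s + 4999))))
  expect_gte(nrow(w1), 50)
  d <- as.matrix(dist(rbind(w1, w2)))
  n1 <- nrow(w1)
  intra <- mean(c(d[1:n1, 1:n1][upper.tri(diag(n1))],
                  d[-(1:n1), -(1:n1)][upper.tri(diag(nrow(w2)))]))
  inter <- mean(d[1:n1, -(1:n1)])
  expect_gt(inter, intra)
})

test_that("proteome pairs plant orthologs at the requested sharing and identity", {
  cfg <- proteome_pair_config(20, target_identity = 1, shared_fraction = 1,
                              seed = 2)
  pp <- simulate_proteome_pair(cfg)
  expect_identical(unname(pp$proteome_a$proteins),
                   unname(pp$proteome_b$proteins))
  expect_equal(nrow(pp$truth), 20L)

  pp3 <- simulate_proteome_pair(
    proteome_pair_config(100, target_identity = 0.9, shared_fraction = 0.3,
                         seed = 3))
  expect_equal(nrow(pp3$truth), 30L)
  expect_equal(length(pp3$proteome_b$proteins), 100L)

  # planted identity measured by global alignment of planted pairs
  pp5 <- simulate_proteome_pair(
    proteome_pair_config(30, target_identity = 0.5, shared_fraction = 1,
                         length_mean = 250, length_min = 200, seed = 4))
  ids <- mapply(function(a, b) {
    al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = "BLOSUM62",
                                        gapOpening = 11, gapExtension = 1,
                                        type = "global")
    Biostrings::pid(al, type = "PID2") / 100
  }, pp5$proteome_a$proteins[pp5$truth$id_a],
     pp5$proteome_b$proteins[pp5$truth$id_b])
  expect_lt(abs(mean(ids) - 0.5), 0.03)
})

test_that("proteome generator output is deterministic and 20-letter", {
  cfg <- proteome_pair_config(10, target_identity = 0.7,
                              shared_fraction = 0.5, seed = 6)
  p1 <- simulate_proteome_pair(cfg)
  p2 <- simulate_proteome_pair(cfg)
  expect_identical(p1$proteome_b$proteins, p2$proteome_b$proteins)
  expect_false(any(grepl("[^ARNDCQEGHILKMFPSTWYV]",
                         c(p1$proteome_a$proteins, p1$proteome_b$proteins))))
})
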