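# Independent oracles and small fixtures built in code.

# Naive full-matrix affine-gap Smith-Waterman (scores only), written as a
# direct transcription of the recursion and kept independent of the
# package's compiled implementation. Gap of length k costs open + k * ext.
naive_sw_score <- function(q, t, S, open = 11, ext = 1) {
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(t, "")[[1]]
  m <- length(qa); n <- length(ta)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + S[qa[i - 1], ta[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Lloyd's k-means iteration from a fixed initial codebook, keeping a
# center unchanged when its cluster is empty.
lloyd_iterate <- function(X, centers, iters) {
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    for (k in seq_len(nrow(centers))) {
      idx <- which(assign == k)
      if (length(idx)) centers[k, ] <- colMeans(X[idx, , drop = FALSE])
    }
  }
  centers
}

# Sort-and-drop threshold oracle, straight from the stated rule.
threshold_oracle <- function(d, drop = 0.02) {
  n <- length(d)
  k <- if (n < 50) 0 else min(ceiling(drop * n), n - 1)
  sort(d, decreasing = TRUE)[k + 1]
}

random_aa <- function(n, len_range = c(8, 30)) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# Small 5-genome community used by the recruitment tests: distinct GC,
# distinct 6-sample abundance profiles, scaffold-level noise.
community_fixture <- function(seed = 11, genome_length = 1.25e6) {
  profiles <- rbind(c(20, 18, 15, 10,  6,  4),
                    c( 3,  6, 12, 18, 22, 25),
                    c(10, 10, 10, 10, 10, 10),
                    c(25,  5, 25,  5, 25,  5),
                    c( 2,  4, 30,  4,  2, 30))
  cc <- community_config(5, genome_length = genome_length,
                         gc_targets = c(0.30, 0.38, 0.46, 0.54, 0.62),
                         abundance_profiles = profiles, seed = seed)
  sc <- simulate_community(cc)
  list(config = cc, scaffolds = sc, abundance = simulate_abundance(cc, sc))
}

# Smaller 3-genome community for pipeline smoke tests.
small_community <- function(seed = 5) {
  profiles <- rbind(c(20, 15, 10, 6, 4, 2),
                    c(2, 5, 10, 16, 22, 26),
                    c(12, 12, 12, 12, 12, 12))
  cc <- community_config(3, genome_length = 2.5e5,
                         gc_targets = c(0.32, 0.45, 0.58),
                         abundance_profiles = profiles, seed = seed)
  sc <- simulate_community(cc)
  list(config = cc, scaffolds = sc, abundance = simulate_abundance(cc, sc))
}

# Split a labelled community into a training set, a target bin and held-out
# candidates (a fixed fraction per genome).
holdout_split <- function(sc, target = "genome_2", frac = 0.2, seed = 99) {
  ids <- names(sc$sequences)
  labs <- sc$labels[ids]
  cand <- parcubin:::with_seed(seed, unlist(lapply(split(ids, labs),
    function(v) sample(v, max(2, round(frac * length(v)))))))
  train <- setdiff(ids, cand)
  list(train = train, candidates = unname(cand),
       bin = train[labs[train] == target],
       truth_pos = unname(cand[labs[cand] == target]))
}

blosum62_ref <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
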