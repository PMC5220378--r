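# Synthetic communities and proteome pairs with known ground truth.

#' Configuration for a synthetic metagenomic community
#'
#' Defines a community of source genomes with distinct tetranucleotide
#' composition (independent seeded order-`markov_order` chains), distinct GC,
#' scaffolds of log-normally distributed length, and a per-genome abundance
#' profile over a short time series of samples with scaffold-level
#' multiplicative coverage noise.
#'
#' @param n_genomes number of source genomes.
#' @param genome_length bases per genome (single value or per-genome vector).
#' @param gc_targets per-genome GC fraction, each strictly in (0, 1).
#' @param abundance_profiles matrix (genomes x samples) of non-negative mean
#'   coverages; each row needs at least one positive entry.
#' @param markov_order Markov chain order for genome composition (default 3,
#'   so 4-mer signatures are genome-specific by construction).
#' @param n_samples number of time points (default 6, a six-sample series).
#' @param scaffold_length_mean mean scaffold length in bases (natural scale).
#' @param scaffold_length_sigma log-scale standard deviation of the scaffold
#'   length law.
#' @param scaffold_min_length minimum scaffold length (>= 5000 so every
#'   scaffold yields at least one analysis window).
#' @param coverage_noise_cv coefficient of variation of per-scaffold
#'   log-normal coverage noise (0 = noiseless).
#' @param seed integer seed; all downstream simulation is a pure function of
#'   the configuration including this seed.
#' @return an object of class `community_config`.
#' @export
community_config <- function(n_genomes, genome_length, gc_targets,
                             abundance_profiles, markov_order = 3L,
                             n_samples = 6L, scaffold_length_mean = 15000,
                             scaffold_length_sigma = 0.45,
                             scaffold_min_length = 5000,
                             coverage_noise_cv = 0.2, seed = 1L) {
  if (n_genomes < 1L) stop_config("n_genomes must be >= 1")
  genome_length <- rep_len(genome_length, n_genomes)
  gc_targets <- rep_len(gc_targets, n_genomes)
  if (any(!is.finite(gc_targets)) || any(gc_targets <= 0) || any(gc_targets >= 1))
    stop_config("gc_targets must be strictly between 0 and 1")
  if (is.list(abundance_profiles))   # e.g. rows from a YAML config
    abundance_profiles <- do.call(rbind, lapply(abundance_profiles,
                                                as.numeric))
  abundance_profiles <- as.matrix(abundance_profiles)
  if (nrow(abundance_profiles) != n_genomes ||
      ncol(abundance_profiles) != n_samples)
    stop_config("abundance_profiles must be a (n_genomes x n_samples) matrix")
  if (any(abundance_profiles < 0) ||
      any(rowSums(abundance_profiles) <= 0))
    stop_config("abundance profiles must be non-negative with at least one ",
                "positive entry per genome")
  if (markov_order < 0L) stop_config("markov_order must be >= 0")
  if (scaffold_min_length < 5000)
    stop_config("scaffold_min_length must be >= 5000")
  if (coverage_noise_cv < 0) stop_config("coverage_noise_cv must be >= 0")
  structure(list(
    n_genomes = as.integer(n_genomes), genome_length = genome_length,
    gc_targets = gc_targets, abundance_profiles = abundance_profiles,
    markov_order = as.integer(markov_order),
    n_samples = as.integer(n_samples),
    scaffold_length_mean = scaffold_length_mean,
    scaffold_length_sigma = scaffold_length_sigma,
    scaffold_min_length = scaffold_min_length,
    coverage_noise_cv = coverage_noise_cv, seed = as.integer(seed)
  ), class = "community_config")
}

#' Simulate a genome sequence from a seeded Markov chain
#'
#' Draws an order-`order` transition matrix from a seeded Dirichlet prior and
#' rescales each context row so the probability of emitting G or C equals
#' `gc` exactly; the emitted sequence then recovers the GC target up to
#' binomial noise while retaining a genome-specific k-mer signature.
#'
#' @param length sequence length in bases (>= 20000).
#' @param gc target GC fraction, strictly in (0, 1).
#' @param order Markov order (0 gives an i.i.d. sequence).
#' @param seed integer seed; identical arguments give identical sequences.
#' @param dirichlet_conc concentration of the Dirichlet prior on transition
#'   rows; smaller values give more genome-specific composition.
#' @return a single nucleotide string.
#' @export
simulate_genome <- function(length, gc, order = 3L, seed = 1L,
                            dirichlet_conc = 12) {
  if (!is.finite(gc) || gc <= 0 || gc >= 1)
    stop_config("gc must be a finite fraction strictly between 0 and 1")
  if (length < 20000) stop_config("genome length must be >= 20 kb")
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (order == 0L) {
    # i.i.d. bases at the strand-symmetric marginal
    return(with_seed(seed, .markov_sequence(as.integer(length), 0L,
                                            matrix(base_probs, 1L),
                                            base_probs)))
  }
  with_seed(seed, {
    ncontext <- 4L^order
    alpha <- dirichlet_conc * base_probs
    trans <- matrix(rgamma(ncontext * 4L, shape = rep(alpha, each = ncontext)),
                    nrow = ncontext)
    trans <- trans / rowSums(trans)
    # pin per-row GC emission probability to the target
    gc_row <- trans[, 2L] + trans[, 3L]
    at_row <- trans[, 1L] + trans[, 4L]
    trans[, c(2L, 3L)] <- trans[, c(2L, 3L)] * gc / gc_row
    trans[, c(1L, 4L)] <- trans[, c(1L, 4L)] * (1 - gc) / at_row
    .markov_sequence(as.integer(length), as.integer(order), trans, base_probs)
  })
}

#' Fragment a genome into contiguous scaffolds
#'
#' Scaffold lengths are drawn from a log-normal law (`mean` on the natural
#' scale, `sigma` on the log scale) truncated below at `min`; a terminal
#' remainder shorter than `min` is merged into the last scaffold. The
#' scaffolds partition the genome: their concatenation reconstructs it.
#'
#' @param sequence genome nucleotide string.
#' @param law list with `mean`, `sigma`, `min` (min >= 5000).
#' @param seed integer seed for the length draws.
#' @param prefix scaffold id prefix.
#' @param label optional genome label applied to every scaffold.
#' @return a [scaffold_set()].
#' @export
fragment_genome <- function(sequence, law = list(mean = 15000, sigma = 0.45,
                                                 min = 5000),
                            seed = 1L, prefix = "scaffold", label = NULL) {
  if (is.null(law$min) || law$min < 5000)
    stop_config("scaffold length law minimum must be >= 5000 bases")
  n <- nchar(sequence)
  if (n < law$min) stop_config("genome shorter than the minimum scaffold length")
  lens <- with_seed(seed, {
    meanlog <- log(law$mean) - law$sigma^2 / 2
    out <- integer(0)
    total <- 0L
    while (total < n) {
      l <- max(law$min, round(rlnorm(1L, meanlog, law$sigma)))
      out <- c(out, as.integer(l))
      total <- total + as.integer(l)
    }
    out
  })
  ends <- pmin(cumsum(as.numeric(lens)), n)
  keep <- which(!duplicated(ends))
  ends <- ends[keep]
  starts <- c(0, ends[-length(ends)])
  # merge a too-short terminal remainder into the previous scaffold
  k <- length(ends)
  if (k > 1L && (ends[k] - starts[k]) < law$min) {
    starts <- starts[-k]
    ends <- ends[-(k - 1L)]
    k <- k - 1L
  }
  seqs <- substring(sequence, starts + 1, ends)
  ids <- sprintf("%s_%d", prefix, seq_len(k))
  names(seqs) <- ids
  labels <- if (!is.null(label)) stats::setNames(rep(label, k), ids)
  scaffold_set(seqs, labels = labels)
}

#' Simulate a full community: genomes, scaffolds and truth labels
#'
#' @param config a [community_config()].
#' @return a [scaffold_set()] whose `labels` record the source genome of
#'   every scaffold (genomes are labelled `genome_1`, `genome_2`, ...).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  sets <- lapply(seq_len(config$n_genomes), function(g) {
    genome <- simulate_genome(config$genome_length[g], config$gc_targets[g],
                              order = config$markov_order,
                              seed = config$seed + 7L * g)
    fragment_genome(genome,
                    law = list(mean = config$scaffold_length_mean,
                               sigma = config$scaffold_length_sigma,
                               min = config$scaffold_min_length),
                    seed = config$seed + 7L * g + 1L,
                    prefix = sprintf("g%d_scaffold", g),
                    label = sprintf("genome_%d", g))
  })
  scaffold_set(do.call(c, lapply(sets, `[[`, "sequences")),
               labels = do.call(c, lapply(sets, `[[`, "labels")))
}

#' Simulate the per-scaffold, per-sample coverage table
#'
#' Coverage of scaffold s (genome g) in sample t is
#' `abundance_profiles[g, t] * noise(s)`, with log-normal scaffold-level
#' noise of the configured coefficient of variation shared across samples,
#' so within-genome time-series shapes stay correlated.
#'
#' @param config a [community_config()].
#' @param scaffolds a labelled [scaffold_set()]; every label must be a
#'   `genome_<g>` present in the config.
#' @param seed seed for the noise draws (default derived from the config).
#' @return numeric matrix (scaffolds x samples).
#' @export
simulate_abundance <- function(config, scaffolds, seed = config$seed + 1000L) {
  stopifnot(inherits(config, "community_config"),
            inherits(scaffolds, "scaffold_set"))
  ids <- names(scaffolds$sequences)
  labs <- scaffolds$labels[ids]
  if (is.null(scaffolds$labels) || anyNA(labs))
    stop_format("every scaffold must carry a genome label")
  g <- as.integer(sub("^genome_", "", labs))
  if (anyNA(g) || any(g < 1L) || any(g > config$n_genomes))
    stop_format("scaffold labelled with a genome absent from the config")
  cv <- config$coverage_noise_cv
  noise <- if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    with_seed(seed, rlnorm(length(ids), meanlog = -sdl^2 / 2, sdlog = sdl))
  } else rep(1, length(ids))
  m <- config$abundance_profiles[g, , drop = FALSE] * noise
  dimnames(m) <- list(ids, paste0("sample_", LETTERS[seq_len(config$n_samples)]))
  m
}

#' Configuration for a synthetic proteome pair
#'
#' @param n_proteins proteins per genome.
#' @param target_identity planted amino-acid identity of shared proteins,
#'   in (0, 1].
#' @param shared_fraction fraction of proteins present in both genomes,
#'   in `[0, 1]`.
#' @param length_mean,length_min protein length law (log-normal mean on the
#'   natural scale; hard minimum).
#' @param length_sigma log-scale sd of protein length.
#' @param indel_rate per-site indel probability applied to shared copies
#'   (default 0: substitution-only divergence).
#' @param seed integer seed.
#' @return an object of class `proteome_pair_config`.
#' @export
proteome_pair_config <- function(n_proteins, target_identity, shared_fraction,
                                 length_mean = 300, length_min = 80,
                                 length_sigma = 0.25, indel_rate = 0,
                                 seed = 1L) {
  if (!is.finite(target_identity) || target_identity <= 0 || target_identity > 1)
    stop_config("target_identity must be in (0, 1]")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop_config("shared_fraction must be in [0, 1]")
  if (n_proteins < 1L) stop_config("n_proteins must be >= 1")
  if (indel_rate < 0 || indel_rate >= 1) stop_config("indel_rate must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 target_identity = target_identity,
                 shared_fraction = shared_fraction,
                 length_mean = length_mean, length_min = length_min,
                 length_sigma = length_sigma, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "proteome_pair_config")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Amino-acid exchangeability weights from BLOSUM62 log-odds: off-diagonal
# substitution b <- a is proposed with weight 2^(S[a,b]/2) (half-bit scores).
exchange_weights <- function() {
  S <- blosum62()[AA20, AA20]
  W <- 2^(S / 2)
  diag(W) <- 0
  W / rowSums(W)
}

random_protein <- function(n_len) {
  vapply(n_len, function(l)
    paste(sample(AA20, l, replace = TRUE), collapse = ""), character(1L))
}

# Substitute single sites (BLOSUM62-exchangeability proposals) until the
# realized identity to the original drops to the target; avoids any
# closed-form back-substitution correction.
mutate_to_identity <- function(seq, target, W) {
  orig <- strsplit(seq, "")[[1L]]
  cur <- orig
  L <- length(orig)
  n_match <- L
  target_matches <- round(target * L)
  while (n_match > target_matches) {
    pos <- sample.int(L, 1L)
    was_match <- cur[pos] == orig[pos]
    cur[pos] <- sample(AA20, 1L, prob = W[cur[pos], ])
    now_match <- cur[pos] == orig[pos]
    n_match <- n_match + (now_match - was_match)
  }
  paste(cur, collapse = "")
}

apply_indels <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  u <- runif(length(ch))
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  ch[ins] <- paste0(ch[ins], sample(AA20, sum(ins), replace = TRUE))
  paste(ch[!del], collapse = "")
}

#' Simulate a proteome pair with planted orthologs
#'
#' Genome A gets `n_proteins` random sequences; a `shared_fraction` of them
#' is copied into genome B and mutated by seeded point substitutions (drawn
#' proportional to BLOSUM62 exchangeabilities) until the realized identity
#' reaches `target_identity`; the remaining B proteins are independent random
#' sequences. The returned truth map records the planted ortholog pairs.
#'
#' @param config a [proteome_pair_config()].
#' @return list with `proteome_a`, `proteome_b` (see [proteome()]) and
#'   `truth`, a data.frame of planted pairs (`id_a`, `id_b`).
#' @export
simulate_proteome_pair <- function(config) {
  stopifnot(inherits(config, "proteome_pair_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    lens <- pmax(config$length_min,
                 round(rlnorm(n, log(config$length_mean) -
                                config$length_sigma^2 / 2,
                              config$length_sigma)))
    a_seqs <- random_protein(lens)
    names(a_seqs) <- sprintf("A|p%03d", seq_len(n))
    n_shared <- round(config$shared_fraction * n)
    W <- exchange_weights()
    b_shared <- character(0)
    if (n_shared > 0) {
      b_shared <- vapply(a_seqs[seq_len(n_shared)], function(s) {
        s2 <- if (config$target_identity < 1)
          mutate_to_identity(s, config$target_identity, W) else s
        apply_indels(s2, config$indel_rate)
      }, character(1L), USE.NAMES = FALSE)
    }
    n_unique <- n - n_shared
    b_lens <- pmax(config$length_min,
                   round(rlnorm(n_unique, log(config$length_mean) -
                                  config$length_sigma^2 / 2,
                                config$length_sigma)))
    b_seqs <- c(b_shared, random_protein(b_lens))
    names(b_seqs) <- sprintf("B|p%03d", seq_len(n))
    truth <- data.frame(id_a = names(a_seqs)[seq_len(n_shared)],
                        id_b = names(b_seqs)[seq_len(n_shared)],
                        stringsAsFactors = FALSE)
    list(proteome_a = proteome("A", a_seqs),
         proteome_b = proteome("B", b_seqs),
         truth = truth)
  })
}
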