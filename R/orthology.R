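# Reciprocal-best-hit orthology from exact Smith-Waterman protein
# alignment, AAI and ortholog-fraction matrices.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","X")

# BLOSUM62 from Biostrings' bundled data, restricted to the 20 amino acids
# plus X; X scores 0 against everything.
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  S["X", ] <- 0L
  S[, "X"] <- 0L
  storage.mode(S) <- "integer"
  S
}

#' Alignment scoring configuration
#'
#' Gapped BLOSUM62 scoring with affine gap cost `gap_open + k * gap_ext`
#' for a gap of length k, and Karlin-Altschul statistics
#' (`E = K * m * n * exp(-lambda * score)`,
#' `bits = (lambda * score - ln K) / ln 2`) with the standard gapped
#' BLOSUM62/11/1 parameters. The ortholog thresholds are inclusive: a hit
#' with bit score exactly `bit_min` or coverage exactly `coverage_min`
#' passes.
#'
#' @param gap_open,gap_ext positive gap penalties (defaults 11, 1).
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267, 0.041).
#' @param evalue_max maximum E-value for a hit (default 0.01).
#' @param bit_min minimum bit score (default 40).
#' @param coverage_min minimum aligned fraction of the protein (default
#'   0.65).
#' @param coverage_mode which protein(s) the coverage test applies to:
#'   `"both"` (default, strictest), `"query"`, or `"shorter"`.
#' @return object of class `scoring_config`.
#' @export
scoring_config <- function(gap_open = 11L, gap_ext = 1L,
                           lambda = 0.267, K = 0.041,
                           evalue_max = 0.01, bit_min = 40,
                           coverage_min = 0.65,
                           coverage_mode = c("both", "query", "shorter")) {
  if (gap_open <= 0 || gap_ext <= 0) stop_config("gap penalties must be positive")
  if (lambda <= 0 || K <= 0) stop_config("lambda and K must be positive")
  structure(list(matrix = blosum62(), gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext), lambda = lambda, K = K,
                 evalue_max = evalue_max, bit_min = bit_min,
                 coverage_min = coverage_min,
                 coverage_mode = match.arg(coverage_mode)),
            class = "scoring_config")
}

#' Construct a proteome
#'
#' @param genome genome id.
#' @param proteins named character vector of amino-acid sequences (20-letter
#'   alphabet plus X).
#' @return object of class `proteome`.
#' @export
proteome <- function(genome, proteins) {
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop_format("protein ids must be present and unique")
  proteins <- toupper(proteins)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), proteins)
  if (any(bad)) {
    i <- which(bad)[1L]
    pos <- regexpr(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                   proteins[i])
    stop_format("illegal residue '", substring(proteins[i], pos, pos),
                "' at position ", pos, " of protein ", names(proteins)[i])
  }
  structure(list(genome = genome, proteins = proteins), class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome", x$genome, ":", length(x$proteins), "proteins,",
      sum(nchar(x$proteins)), "residues\n")
  invisible(x)
}

#' Read a protein FASTA into a proteome
#' @param path protein FASTA file.
#' @param genome genome id (default: file name without extension).
#' @export
read_proteome <- function(path, genome = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  proteome(genome, seqs)
}

#' Write a proteome as protein FASTA
#' @param p a [proteome()].
#' @param path output path.
#' @export
write_proteome <- function(p, path) {
  stopifnot(inherits(p, "proteome"))
  write_fasta(p$proteins, path)
}

encode_aa <- function(seqs, alphabet = AA_ALPHABET) {
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    idx <- match(ch, alphabet)
    if (anyNA(idx))
      stop_format("illegal residue '", ch[which(is.na(idx))[1L]],
                  "' at position ", which(is.na(idx))[1L])
    idx - 1L
  })
}

#' Exact local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps under the configured scoring. Identity is
#' the percentage of identical residues over the aligned residue-residue
#' columns (gap columns excluded); coverages are the local alignment span
#' divided by each protein's full length.
#'
#' @param query,target amino-acid strings.
#' @param scoring a [scoring_config()].
#' @return list of class `alignment_result`: `score`, `bit_score`,
#'   `e_value`, `identity` (percent), `coverage_query`, `coverage_target`,
#'   span coordinates (0-based, half-open) and aligned column counts.
#' @export
align <- function(query, target, scoring = scoring_config()) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop_format("empty sequence")
  enc <- encode_aa(c(query, target))
  r <- .sw_pair(enc[[1L]], enc[[2L]], scoring$matrix,
                scoring$gap_open, scoring$gap_ext)
  m <- nchar(query); n <- nchar(target)
  structure(list(
    score = r$score,
    bit_score = bit_score(r$score, scoring),
    e_value = e_value(r$score, m, n, scoring),
    identity = if (r$cols > 0) 100 * r$ident / r$cols else 0,
    coverage_query = (r$qend - r$qstart) / m,
    coverage_target = (r$tend - r$tstart) / n,
    qstart = r$qstart, qend = r$qend,
    tstart = r$tstart, tend = r$tend,
    aligned_cols = r$cols, identical_cols = r$ident
  ), class = "alignment_result")
}

bit_score <- function(raw, scoring)
  (scoring$lambda * raw - log(scoring$K)) / log(2)

e_value <- function(raw, m, n, scoring)
  scoring$K * (as.numeric(m) * as.numeric(n)) * exp(-scoring$lambda * raw)

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment: raw %d, %.1f bits, E %.3g, identity %.1f%%, cov %.2f/%.2f\n",
    x$score, x$bit_score, x$e_value, x$identity,
    x$coverage_query, x$coverage_target))
  invisible(x)
}

# All-vs-all hit table between two proteomes: one row per pair passing the
# E-value / bit-score / coverage thresholds, with per-pair statistics.
hit_table <- function(pa, pb, scoring) {
  ea <- encode_aa(pa$proteins)
  eb <- encode_aa(pb$proteins)
  r <- .sw_all(ea, eb, scoring$matrix, scoring$gap_open, scoring$gap_ext)
  la <- nchar(pa$proteins); lb <- nchar(pb$proteins)
  mn <- outer(as.numeric(la), as.numeric(lb))
  bits <- bit_score(r$score, scoring)
  ev <- scoring$K * mn * exp(-scoring$lambda * r$score)
  cov_a <- r$qspan / la
  cov_b <- sweep(r$tspan, 2L, lb, "/")
  cov_ok <- switch(scoring$coverage_mode,
    both = cov_a >= scoring$coverage_min & cov_b >= scoring$coverage_min,
    query = cov_a >= scoring$coverage_min,
    shorter = ifelse(outer(la, lb, "<="), cov_a, cov_b) >= scoring$coverage_min)
  pass <- bits >= scoring$bit_min & ev <= scoring$evalue_max & cov_ok
  idx <- which(pass, arr.ind = TRUE)
  ident_pct <- ifelse(r$cols > 0, 100 * r$ident / r$cols, 0)
  data.frame(
    a = names(pa$proteins)[idx[, 1L]],
    b = names(pb$proteins)[idx[, 2L]],
    bit = bits[idx], evalue = ev[idx],
    identity = ident_pct[idx],
    cov_a = cov_a[idx], cov_b = cov_b[idx],
    stringsAsFactors = FALSE)
}

# best hit per `from` protein: max bit, ties by higher identity then
# lexicographic target id
best_by <- function(hits, from, to) {
  if (nrow(hits) == 0L)
    return(stats::setNames(character(0), character(0)))
  o <- order(hits[[from]], -hits$bit, -hits$identity, hits[[to]])
  h <- hits[o, ]
  h <- h[!duplicated(h[[from]]), ]
  stats::setNames(h[[to]], h[[from]])
}

#' Best cross-genome hit for every protein
#'
#' For each protein in `pa`, the protein in `pb` with the highest bit score
#' among hits passing the E-value, bit-score and coverage thresholds; ties
#' are broken by higher identity, then lexicographic target id. Proteins
#' with no passing hit are absent from the map.
#'
#' @param pa,pb [proteome()] objects.
#' @param scoring a [scoring_config()].
#' @return named character vector: best target id per query id.
#' @export
best_hits <- function(pa, pb, scoring = scoring_config()) {
  best_by(hit_table(pa, pb, scoring), "a", "b")
}

#' Reciprocal-best-hit ortholog table for a genome pair
#'
#' A pair (a, b) is an ortholog pair iff b is a's best hit and a is b's
#' best hit, under inclusive thresholds E <= 0.01, bit >= 40 and aligned
#' coverage >= 0.65 of the protein sequence (both proteins by default).
#' Because local alignment scores are symmetric, one all-vs-all pass
#' serves both directions.
#'
#' @param pa,pb [proteome()] objects.
#' @param scoring a [scoring_config()].
#' @return object of class `ortholog_table`: `pairs` data.frame
#'   (`id_a`, `id_b`, `identity`, `bit`, `evalue`, `cov_a`, `cov_b`),
#'   genome ids, and the two best-hit maps.
#' @export
rbh <- function(pa, pb, scoring = scoring_config()) {
  stopifnot(inherits(pa, "proteome"), inherits(pb, "proteome"))
  hits <- hit_table(pa, pb, scoring)
  ab <- best_by(hits, "a", "b")
  ba <- best_by(hits, "b", "a")
  mutual <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  key <- paste(mutual, ab[mutual])
  pairs <- hits[match(key, paste(hits$a, hits$b)), ]
  pairs <- data.frame(id_a = pairs$a, id_b = pairs$b,
                      identity = pairs$identity, bit = pairs$bit,
                      evalue = pairs$evalue, cov_a = pairs$cov_a,
                      cov_b = pairs$cov_b, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(genome_a = pa$genome, genome_b = pb$genome,
                 pairs = pairs, best_ab = ab, best_ba = ba),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("ortholog_table %s vs %s: %d reciprocal best-hit pairs\n",
              x$genome_a, x$genome_b, nrow(x$pairs)))
  if (nrow(x$pairs) > 0)
    cat(sprintf("  mean identity %.1f%%\n", mean(x$pairs$identity)))
  invisible(x)
}

#' Average amino-acid identity of an ortholog table
#'
#' Unweighted mean of per-pair percent identity (one alignment per
#' reciprocal pair). Full precision is returned; matrix output rounds to
#' integers.
#'
#' @param x an `ortholog_table` from [rbh()].
#' @return AAI in percent.
#' @export
aai <- function(x) {
  stopifnot(inherits(x, "ortholog_table"))
  if (nrow(x$pairs) == 0L)
    stop_format("AAI undefined: no ortholog pairs between ",
                x$genome_a, " and ", x$genome_b)
  mean(x$pairs$identity)
}

#' All-pairs genome comparison: AAI and ortholog-fraction matrices
#'
#' Runs [rbh()] once per unordered genome pair. The AAI matrix is symmetric
#' with a masked (NA) diagonal; the ortholog-fraction matrix entry (i, j) is
#' `100 * n_pairs / n_proteins(genome i)` and need not be symmetric.
#'
#' @param proteomes list of [proteome()] objects (>= 2, unique genome ids).
#' @param scoring a [scoring_config()].
#' @return object of class `comparison_matrices`: `aai`, `ortho_frac`
#'   (full precision), genome ids and the per-pair `ortholog_table`s.
#' @export
compare_genomes <- function(proteomes, scoring = scoring_config()) {
  stopifnot(length(proteomes) >= 2L)
  ids <- vapply(proteomes, `[[`, character(1L), "genome")
  if (anyDuplicated(ids)) stop_config("genome ids must be unique")
  n <- length(proteomes)
  A <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  FR <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  tables <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    tab <- rbh(proteomes[[i]], proteomes[[j]], scoring)
    tables[[paste(ids[i], ids[j], sep = "|")]] <- tab
    np <- nrow(tab$pairs)
    A[i, j] <- A[j, i] <- if (np > 0) mean(tab$pairs$identity) else NA_real_
    FR[i, j] <- 100 * np / length(proteomes[[i]]$proteins)
    FR[j, i] <- 100 * np / length(proteomes[[j]]$proteins)
  }
  structure(list(genomes = ids, aai = A, ortho_frac = FR, tables = tables),
            class = "comparison_matrices")
}

#' @export
print.comparison_matrices <- function(x, ...) {
  cat("AAI (%, rounded):\n")
  print(round(x$aai))
  cat("orthologous ORFs (%, rounded; row genome's ORFs as denominator):\n")
  print(round(x$ortho_frac))
  invisible(x)
}

#' Shared / unique gene partition of a focal proteome
#'
#' Splits the focal genome's proteins into those with an ortholog in at
#' least one comparison genome (shared) and the complement (unique).
#'
#' @param focal the focal [proteome()].
#' @param tables list of `ortholog_table`s, each involving the focal genome.
#' @return list with `shared` and `unique` (character vectors of protein
#'   ids); their union is the full proteome and they are disjoint.
#' @export
gene_partition <- function(focal, tables) {
  stopifnot(inherits(focal, "proteome"))
  shared <- character(0)
  for (tab in tables) {
    stopifnot(inherits(tab, "ortholog_table"))
    if (tab$genome_a == focal$genome) shared <- c(shared, tab$pairs$id_a)
    else if (tab$genome_b == focal$genome) shared <- c(shared, tab$pairs$id_b)
    else stop_format("ortholog table ", tab$genome_a, " vs ", tab$genome_b,
                     " does not involve focal genome ", focal$genome)
  }
  shared <- intersect(names(focal$proteins), unique(shared))
  list(shared = shared, unique = setdiff(names(focal$proteins), shared))
}
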