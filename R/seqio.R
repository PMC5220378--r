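#' Construct a scaffold set
#'
#' A scaffold set is the package's container for assembled nucleotide
#' scaffolds: a named character vector of sequences (alphabet A, C, G, T, N
#' after uppercasing) plus an optional scaffold-to-genome label map used as
#' synthetic ground truth.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param labels optional named character vector mapping scaffold ids to
#'   genome labels; names must be a subset of the scaffold ids.
#' @return an object of class `scaffold_set`.
#' @export
scaffold_set <- function(sequences, labels = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop_format("all scaffolds must have non-empty ids")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_format("duplicate scaffold id: ", dup[1L])
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L))
    stop_format("empty sequence for scaffold: ",
                ids[which(nchar(sequences) == 0L)[1L]])
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(sequences[i], regexpr("[^ACGTN]", sequences[i]))
    stop_format("illegal character '", ch, "' in scaffold ", ids[i],
                " (DNA alphabet ACGTN only)")
  }
  if (!is.null(labels)) {
    if (is.null(names(labels)) || !all(names(labels) %in% ids))
      stop_format("labels must be named by scaffold ids present in the set")
  }
  structure(list(sequences = sequences, labels = labels),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("scaffold_set:", length(x$sequences), "scaffolds,",
      sum(nchar(x$sequences)), "bp total")
  if (!is.null(x$labels))
    cat(",", length(unique(x$labels)), "genome labels")
  cat("\n")
  invisible(x)
}

#' @export
length.scaffold_set <- function(x) length(x$sequences)

#' Read a nucleotide FASTA file into a scaffold set
#'
#' Records are uppercased and validated: ids must be unique, sequences
#' non-empty and restricted to A/C/G/T/N (U is rejected; DNA only).
#'
#' @param path path to a FASTA file.
#' @return a [scaffold_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  scaffold_set(seqs)
}

#' Write a scaffold set (or named sequences) to FASTA
#'
#' @param x a [scaffold_set()] or a named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "scaffold_set")) x$sequences else x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Basic assembly statistics for a scaffold set
#'
#' GC percent is computed over unambiguous bases only (N excluded from the
#' denominator). N50 is the smallest scaffold length at which the cumulative
#' sum of lengths, sorted descending, first reaches at least half the total
#' assembly length.
#'
#' @param set a [scaffold_set()].
#' @return a list of class `genome_stats` with `n_scaffolds`, `total_length`,
#'   `gc_percent` and `n50`.
#' @export
genome_stats <- function(set) {
  stopifnot(inherits(set, "scaffold_set"))
  if (length(set) == 0L) stop_format("empty scaffold set")
  ss <- Biostrings::DNAStringSet(set$sequences)
  freq <- Biostrings::alphabetFrequency(ss, baseOnly = TRUE)
  acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  denom <- sum(acgt)
  if (denom == 0L) stop_format("GC undefined: no unambiguous bases")
  lens <- nchar(set$sequences)
  structure(list(
    n_scaffolds  = length(lens),
    total_length = sum(lens),
    gc_percent   = 100 * (acgt[["G"]] + acgt[["C"]]) / denom,
    n50          = n50(lens)
  ), class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("scaffolds: %d  total: %d bp  GC: %.1f%%  N50: %d bp\n",
              x$n_scaffolds, x$total_length, x$gc_percent, x$n50))
  invisible(x)
}

n50 <- function(lengths) {
  lengths <- sort(unname(lengths), decreasing = TRUE)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]]
}

#' Read a per-scaffold, per-sample coverage table
#'
#' Expects a TSV whose header is `scaffold` followed by sample names, one row
#' per scaffold, numeric coverage values >= 0.
#'
#' @param path path to the TSV.
#' @param scaffolds optional [scaffold_set()]; scaffolds present in the table
#'   but absent from the set trigger a warning (rows are kept).
#' @return numeric matrix, rownames scaffold ids, one column per sample.
#' @export
read_abundance <- function(path, scaffolds = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  if (length(first) < 2L || first[1L] != "scaffold")
    stop_format("missing or malformed header: expected 'scaffold<TAB>sample...' in ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1L, drop = FALSE])),
           nrow = nrow(tab),
           dimnames = list(tab[[1L]], colnames(tab)[-1L])))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_format("non-numeric coverage value at scaffold ",
                rownames(m)[bad[1L]], ", sample ", colnames(m)[bad[2L]])
  }
  if (any(m < 0)) stop_format("negative coverage values in ", path)
  if (!is.null(scaffolds)) {
    extra <- setdiff(rownames(m), names(scaffolds$sequences))
    if (length(extra))
      warning("abundance table has ", length(extra),
              " scaffold(s) absent from the FASTA (kept): ",
              paste(head(extra, 3L), collapse = ", "),
              if (length(extra) > 3L) ", ..." else "")
  }
  m
}

#' Write an abundance matrix as TSV (`scaffold` + sample columns)
#' @param m numeric matrix with scaffold rownames.
#' @param path output path.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(scaffold = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column `scaffold genome` label TSV into a named vector
#' @param path path to the TSV (header `scaffold<TAB>genome`).
#' @return named character vector: genome label per scaffold id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (ncol(tab) < 2L || colnames(tab)[1L] != "scaffold")
    stop_format("expected header 'scaffold<TAB>genome' in ", path)
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write scaffold labels as a two-column TSV
#' @param labels named character vector (scaffold id -> genome).
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(scaffold = names(labels), genome = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
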