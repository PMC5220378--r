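# Feature space for map-based binning: canonical tetranucleotide
# frequencies over 5 kb windows plus a weighted abundance block.

#' The 136 canonical tetranucleotides
#'
#' Each of the 256 4-mers is mapped to the lexicographically smaller of
#' itself and its reverse complement, collapsing strand: 16 palindromic plus
#' 120 paired keys give 136 canonical tetramers.
#'
#' @return ordered character vector of the 136 canonical 4-mers.
#' @export
canonical_tetramers <- function() {
  all4 <- all_tetramers()
  sort(unique(pmin(all4, revcomp(all4))))
}

all_tetramers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1]
  apply(g, 1L, paste, collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]),
                                     collapse = ""), character(1L),
                USE.NAMES = FALSE))
}

#' Canonical form of a 4-mer
#' @param kmer character vector of 4-mers.
#' @return the lexicographically smaller of each 4-mer and its reverse
#'   complement.
#' @export
canonical_kmer <- function(kmer) pmin(toupper(kmer), revcomp(toupper(kmer)))

#' Non-overlapping analysis windows over a scaffold
#'
#' Consecutive 5000-base windows; a terminal remainder of at least half a
#' window (2500 bases) becomes its own window, a shorter remainder is merged
#' into the final window. Scaffolds shorter than 2500 bases yield no windows.
#' Coordinates are 0-based, half-open.
#'
#' @param length scaffold length in bases.
#' @param window window size (default 5000).
#' @param min_fragment minimum fragment size (default `window / 2`).
#' @return two-column integer matrix of (start, end) pairs; zero rows for
#'   scaffolds below `min_fragment`.
#' @export
scaffold_windows <- function(length, window = 5000L, min_fragment = window %/% 2L) {
  if (length < min_fragment)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  if (length < window)
    return(matrix(c(0L, as.integer(length)), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  n_full <- length %/% window
  rem <- length %% window
  starts <- seq.int(0L, by = window, length.out = n_full)
  ends <- starts + window
  if (rem >= min_fragment) {
    starts <- c(starts, n_full * window)
    ends <- c(ends, length)
  } else if (rem > 0L) {
    ends[n_full] <- length   # merge short remainder into the final window
  }
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Canonical tetranucleotide frequencies of a sequence
#'
#' Counts every overlapping 4-mer containing no N under its canonical key
#' and divides by the number of counted 4-mers. The result is strand
#' invariant: `tetra_frequencies(s)` equals
#' `tetra_frequencies(revcomp(s))`.
#'
#' @param sequence nucleotide string (length >= 4).
#' @return named 136-vector of frequencies (zero vector if no valid 4-mer).
#' @export
tetra_frequencies <- function(sequence) {
  stopifnot(nchar(sequence) >= 4L)
  tetra_matrix(Biostrings::DNAStringSet(toupper(sequence)))[1L, ]
}

# 4-mer frequency matrix (rows = sequences, cols = 136 canonical keys).
# oligonucleotideFrequency tabulates only A/C/G/T words, so 4-mers touching
# an N are never counted.
tetra_matrix <- function(dss) {
  counts <- Biostrings::oligonucleotideFrequency(dss, width = 4L)
  canon <- canonical_kmer(colnames(counts))
  keys <- canonical_tetramers()
  folded <- vapply(keys, function(k)
    rowSums(counts[, canon == k, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L) folded <- matrix(folded, nrow = 1L,
                                           dimnames = list(NULL, keys))
  tot <- rowSums(folded)
  out <- folded / ifelse(tot > 0, tot, 1)
  colnames(out) <- keys
  out
}

#' Build the combined composition + abundance feature table
#'
#' Cuts every scaffold into windows (see [scaffold_windows()]), computes
#' canonical 4-mer frequencies per window, attaches the scaffold's per-sample
#' abundance (optionally log10(x+1)-transformed), z-scores every column over
#' all fragments, and multiplies the abundance block by `weight` (default 5,
#' weighting abundance five-fold relative to composition). Normalization
#' parameters are stored so held-out scaffolds can be projected into the same
#' space with [transform_features()].
#'
#' @param scaffolds a [scaffold_set()].
#' @param abundance numeric matrix (scaffold x sample); every retained
#'   scaffold must have a row.
#' @param weight scalar multiplier for the abundance block after z-scoring.
#' @param window,min_fragment window geometry in bases.
#' @param abundance_transform `"log10p1"` (default) or `"none"`.
#' @return an object of class `feature_table`: fragment metadata, the
#'   combined (fragments x (136 + S)) matrix, and normalization parameters.
#' @export
build_features <- function(scaffolds, abundance, weight = 5,
                           window = 5000L, min_fragment = window %/% 2L,
                           abundance_transform = c("log10p1", "none")) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  abundance_transform <- match.arg(abundance_transform)
  frag <- fragment_scaffolds(scaffolds, abundance, window, min_fragment)
  tetra <- tetra_matrix(frag$dss)
  ab <- abundance[frag$meta$scaffold, , drop = FALSE]
  if (abundance_transform == "log10p1") ab <- log10(ab + 1)
  colnames(ab) <- colnames(abundance)

  zs <- function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2L, sd)
    zero <- sdv == 0 | !is.finite(sdv)
    if (any(zero))
      log_msg("build_features: ", sum(zero),
              " zero-variance column(s); sd set to 1 (columns become 0)")
    sdv[zero] <- 1
    list(z = sweep(sweep(m, 2L, mu), 2L, sdv, "/"), mu = mu, sd = sdv)
  }
  zt <- zs(tetra)
  za <- zs(ab)
  combined <- cbind(zt$z, za$z * weight)
  rownames(combined) <- NULL
  structure(list(
    fragments = frag$meta, combined = combined,
    tetra_cols = seq_len(ncol(tetra)),
    abund_cols = ncol(tetra) + seq_len(ncol(ab)),
    centers = c(zt$mu, za$mu), sds = c(zt$sd, za$sd),
    weight = weight, window = as.integer(window),
    min_fragment = as.integer(min_fragment),
    abundance_transform = abundance_transform,
    samples = colnames(abundance)
  ), class = "feature_table")
}

fragment_scaffolds <- function(scaffolds, abundance, window, min_fragment) {
  ids <- names(scaffolds$sequences)
  lens <- nchar(scaffolds$sequences)
  short <- lens < min_fragment
  if (any(short))
    warning(sum(short), " scaffold(s) below ", min_fragment,
            " bases excluded from the feature table: ",
            paste(head(ids[short], 3L), collapse = ", "),
            if (sum(short) > 3L) ", ..." else "")
  keep <- ids[!short]
  missing <- setdiff(keep, rownames(abundance))
  if (length(missing))
    stop_format("no abundance row for scaffold(s): ",
                paste(head(missing, 3L), collapse = ", "))
  pieces <- lapply(keep, function(id) {
    w <- scaffold_windows(lens[[id]], window, min_fragment)
    data.frame(scaffold = id, window = seq_len(nrow(w)) - 1L,
               start = w[, 1L], end = w[, 2L], stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, pieces)
  if (is.null(meta) || nrow(meta) == 0L)
    stop_format("no scaffold long enough to yield a window")
  rownames(meta) <- NULL
  dss <- Biostrings::DNAStringSet(substring(scaffolds$sequences[meta$scaffold],
                                            meta$start + 1L, meta$end))
  list(meta = meta, dss = dss)
}

#' Project held-out scaffolds into a fitted feature space
#'
#' Applies the window rule, the abundance transform and the stored
#' normalization (means, sds, weight) of a fitted [build_features()] table
#' to new scaffolds. Scaffolds too short to yield a window are skipped with
#' a warning.
#'
#' @param fit a `feature_table` from [build_features()].
#' @param scaffolds new [scaffold_set()].
#' @param abundance abundance matrix covering the new scaffolds.
#' @return a `feature_table` in the same space as `fit`.
#' @export
transform_features <- function(fit, scaffolds, abundance) {
  stopifnot(inherits(fit, "feature_table"))
  frag <- fragment_scaffolds(scaffolds, abundance, fit$window, fit$min_fragment)
  tetra <- tetra_matrix(frag$dss)
  ab <- abundance[frag$meta$scaffold, fit$samples, drop = FALSE]
  if (fit$abundance_transform == "log10p1") ab <- log10(ab + 1)
  raw <- cbind(tetra, ab)
  z <- sweep(sweep(raw, 2L, fit$centers), 2L, fit$sds, "/")
  z[, fit$abund_cols] <- z[, fit$abund_cols] * fit$weight
  rownames(z) <- NULL
  out <- fit
  out$fragments <- frag$meta
  out$combined <- z
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$combined), "fragments x",
      ncol(x$combined), "features (", length(x$tetra_cols),
      "tetra +", length(x$abund_cols), "abundance, weight",
      x$weight, ")\n")
  invisible(x)
}
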