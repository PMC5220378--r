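# Completeness / contamination from a universal single-copy marker inventory.

#' Read a marker-id list (one id per line)
#'
#' The package ships a default 43-id universal single-copy set suitable for
#' small reduced genomes at
#' `system.file("extdata", "cpr_markers43.txt", package = "parcubin")`.
#' The list is configuration, not code: edit or replace it to match the
#' marker collection in use.
#'
#' @param path text file, one marker id per line; blank lines and `#`
#'   comments ignored.
#' @return character vector of marker ids.
#' @export
read_marker_set <- function(path = system.file("extdata", "cpr_markers43.txt",
                                               package = "parcubin")) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (anyDuplicated(ids)) stop_format("duplicate marker id: ",
                                      ids[duplicated(ids)][1L])
  if (length(ids) == 0L) stop_format("empty marker set: ", path)
  ids
}

#' Read a marker hit table into an inventory
#'
#' @param path TSV with columns `gene_id`, `marker_id`, `score` (header
#'   required). Hits below `min_score` are discarded before counting.
#' @param min_score optional score threshold.
#' @return named integer vector of hit counts per marker id.
#' @export
read_marker_hits <- function(path, min_score = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) return(stats::setNames(integer(0), character(0)))
  header <- strsplit(lines[1L], "\t")[[1L]]
  if (length(header) < 3L || header[1L] != "gene_id")
    stop_format("expected header 'gene_id<TAB>marker_id<TAB>score' in ", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(body, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_format("malformed row at line ", bad[1L] + 1L, " of ", path)
  marker <- vapply(parts, `[[`, character(1L), 2L)
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1L), 3L)))
  if (anyNA(score))
    stop_format("non-numeric score at line ", which(is.na(score))[1L] + 1L,
                " of ", path)
  if (!is.null(min_score)) {
    keep <- score >= min_score
    marker <- marker[keep]
  }
  tab <- table(marker)
  stats::setNames(as.integer(tab), names(tab))
}

#' Genome completeness and duplication from a marker inventory
#'
#' Completeness is the percentage of the marker set detected at least once;
#' markers seen two or more times are reported as a contamination signal.
#'
#' @param inventory named integer vector of per-marker hit counts (keys must
#'   all belong to `markers`).
#' @param markers character vector of expected single-copy marker ids.
#' @return object of class `scg_completeness`: `percent`, `present`,
#'   `missing`, `multi_copy`.
#' @export
completeness <- function(inventory, markers = read_marker_set()) {
  stopifnot(is.character(markers), length(markers) > 0L)
  unknown <- setdiff(names(inventory), markers)
  if (length(unknown))
    stop_format("inventory contains unknown marker id: ", unknown[1L])
  counts <- stats::setNames(integer(length(markers)), markers)
  counts[names(inventory)] <- as.integer(inventory)
  present <- names(counts)[counts >= 1L]
  structure(list(
    percent = 100 * length(present) / length(markers),
    present = present,
    missing = setdiff(markers, present),
    multi_copy = names(counts)[counts >= 2L],
    counts = counts
  ), class = "scg_completeness")
}

#' @export
print.scg_completeness <- function(x, ...) {
  cat(sprintf("completeness: %.1f%% (%d/%d markers; %d missing, %d multi-copy)\n",
              x$percent, length(x$present),
              length(x$present) + length(x$missing),
              length(x$missing), length(x$multi_copy)))
  invisible(x)
}
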