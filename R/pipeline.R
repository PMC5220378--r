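# Pipeline runners: feature building -> SOM -> threshold -> recruit ->
# confirm, and the all-pairs genome comparison, each with a reproducibility
# manifest.

#' Subset a scaffold set by id
#' @param set a [scaffold_set()].
#' @param ids scaffold ids to keep.
#' @export
subset_scaffolds <- function(set, ids) {
  stopifnot(inherits(set, "scaffold_set"))
  missing <- setdiff(ids, names(set$sequences))
  if (length(missing))
    stop_format("scaffold id(s) not in set: ", paste(head(missing, 3L),
                                                     collapse = ", "))
  scaffold_set(set$sequences[ids],
               labels = if (!is.null(set$labels))
                 set$labels[intersect(ids, names(set$labels))])
}

default_refine_config <- function() {
  list(
    window = 5000L, min_fragment = 2500L, weight = 5,
    abundance_transform = "log10p1",
    som = list(rows = NULL, cols = NULL, epochs = 10L,
               topology = "toroidal", init = "pca",
               radius0 = NULL, radius_final = 1, seed = 1L),
    drop = 0.02, aggregate = "min", confirm_seed = 2L
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, params) {
  params$package_version <- as.character(utils::packageVersion("parcubin"))
  jsonlite::write_json(params, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Run the full bin-refinement pipeline
#'
#' features -> SOM training -> percentile threshold -> recruitment ->
#' confirmatory retraining. Inputs may be file paths (`fasta`, `abundance`
#' TSV, `bin` id list) or in-memory objects. Candidate scaffolds default to
#' every non-bin scaffold in the input (which then also participate in
#' training, as on a full-community map); pass `candidates` to hold a set
#' out of training instead. All outputs (manifest, report, codebook, BMU,
#' U-matrix and recruitment TSVs) are written under `outdir` and are
#' byte-reproducible at fixed seeds.
#'
#' @param config list (or YAML path) with entries `fasta`, `abundance`,
#'   `bin`, optional `candidates`, `outdir`, and any of the defaults:
#'   `window` (5000), `min_fragment` (2500), `weight` (5),
#'   `abundance_transform`, `som` (grid, `epochs` 10, `topology`, `init`,
#'   radii, `seed`), `drop` (0.02), `aggregate`, `confirm_seed`.
#' @return (invisibly) list with the fitted model, threshold, recruitment
#'   and confirmed scaffold ids.
#' @export
run_refine <- function(config) {
  cfg <- utils::modifyList(default_refine_config(), load_config(config))
  for (field in c("fasta", "abundance", "bin"))
    if (is.null(cfg[[field]]))
      stop_config("run_refine config requires '", field, "'")
  outdir <- cfg$outdir %||% "refine_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  cat("", file = logf)

  scaffolds <- if (inherits(cfg$fasta, "scaffold_set")) cfg$fasta else {
    if (!file.exists(cfg$fasta)) stop_format("missing FASTA: ", cfg$fasta)
    read_fasta(cfg$fasta)
  }
  abund <- if (is.matrix(cfg$abundance)) cfg$abundance else {
    if (!file.exists(cfg$abundance))
      stop_format("missing abundance table: ", cfg$abundance)
    read_abundance(cfg$abundance, scaffolds)
  }
  bin <- if (is.character(cfg$bin) && length(cfg$bin) == 1L &&
             file.exists(cfg$bin)) readLines(cfg$bin) else cfg$bin
  bin <- bin[nzchar(bin)]
  log_msg("run_refine: ", length(scaffolds), " scaffolds, bin of ",
          length(bin), " scaffolds", file = logf)

  held_out <- !is.null(cfg$candidates)
  cand_ids <- if (held_out) {
    ids <- if (is.character(cfg$candidates) && length(cfg$candidates) == 1L &&
               file.exists(cfg$candidates)) readLines(cfg$candidates)
           else cfg$candidates
    ids[nzchar(ids)]
  } else setdiff(names(scaffolds$sequences), bin)
  train_ids <- if (held_out)
    setdiff(names(scaffolds$sequences), cand_ids)
  else names(scaffolds$sequences)

  ft <- build_features(subset_scaffolds(scaffolds, train_ids), abund,
                       weight = cfg$weight, window = cfg$window,
                       min_fragment = cfg$min_fragment,
                       abundance_transform = cfg$abundance_transform)
  s <- cfg$som
  model <- esom(ft, rows = s$rows, cols = s$cols, epochs = s$epochs,
                topology = s$topology, init = s$init, radius0 = s$radius0,
                radius_final = s$radius_final, seed = s$seed)
  log_msg(sprintf("run_refine: SOM %dx%d, QE %.4f", model$rows, model$cols,
                  model$quantization_error), file = logf)

  thr <- recruitment_threshold(model, bin = bin, drop = cfg$drop)
  cand_ft <- transform_features(ft, subset_scaffolds(scaffolds, cand_ids),
                                abund)
  rec <- recruit(model, cand_ft, bin, thr, aggregate = cfg$aggregate)
  confirmed <- confirm(ft, cand_ft, bin, rec$recruited,
                       rows = model$rows, cols = model$cols,
                       epochs = s$epochs, topology = s$topology,
                       init = s$init, radius0 = s$radius0,
                       radius_final = s$radius_final,
                       seed = cfg$confirm_seed)
  log_msg("run_refine: threshold ", format(thr), ", recruited ",
          length(rec$recruited), ", confirmed ", length(confirmed),
          file = logf)

  # outputs
  write_tsv(data.frame(neuron = seq_len(nrow(model$codebook)),
                       model$codebook, check.names = FALSE),
            file.path(outdir, "codebook.tsv"))
  write_tsv(cbind(model$fragments[, c("scaffold", "window")],
                  neuron = model$bmu$neuron,
                  distance = model$bmu$distance),
            file.path(outdir, "bmu.tsv"))
  write_tsv(as.data.frame(umatrix(model)), file.path(outdir, "umatrix.tsv"))
  write_tsv(data.frame(scaffold = names(rec$distances),
                       distance = unname(rec$distances),
                       decision = ifelse(names(rec$distances) %in% confirmed,
                                         "confirmed",
                                  ifelse(names(rec$distances) %in%
                                           rec$recruited, "recruited",
                                         "rejected"))),
            file.path(outdir, "recruitment.tsv"))

  stats_before <- genome_stats(subset_scaffolds(scaffolds,
                                                intersect(bin, names(scaffolds$sequences))))
  stats_after <- genome_stats(subset_scaffolds(scaffolds,
                                               union(bin, confirmed)))
  report <- c(
    sprintf("bin scaffolds: %d", length(bin)),
    sprintf("candidates: %d (%s)", length(cand_ids),
            if (held_out) "held out of training" else "on the training map"),
    sprintf("recruitment threshold (drop %.2f): %.6f", cfg$drop, thr),
    sprintf("recruited: %d  confirmed: %d", length(rec$recruited),
            length(confirmed)),
    sprintf("bin before: %d scaffolds, %d bp, GC %.1f%%",
            stats_before$n_scaffolds, stats_before$total_length,
            stats_before$gc_percent),
    sprintf("bin after:  %d scaffolds, %d bp, GC %.1f%%",
            stats_after$n_scaffolds, stats_after$total_length,
            stats_after$gc_percent))
  writeLines(report, file.path(outdir, "report.txt"))
  write_manifest(outdir, list(
    inputs = list(fasta = if (is.character(cfg$fasta)) cfg$fasta else "in-memory",
                  abundance = if (is.character(cfg$abundance)) cfg$abundance
                              else "in-memory",
                  n_scaffolds = length(scaffolds), n_bin = length(bin),
                  n_candidates = length(cand_ids)),
    window = cfg$window, min_fragment = cfg$min_fragment,
    weight = cfg$weight, abundance_transform = cfg$abundance_transform,
    som = list(rows = model$rows, cols = model$cols, epochs = s$epochs,
               topology = s$topology, init = s$init,
               radius0 = model$radius0, radius_final = model$radius_final,
               seed = s$seed),
    drop = cfg$drop, aggregate = cfg$aggregate,
    confirm_seed = cfg$confirm_seed))

  invisible(list(model = model, features = ft, threshold = thr,
                 recruitment = rec, confirmed = confirmed,
                 report = report, outdir = outdir))
}

#' Run the all-pairs genome comparison
#'
#' Computes AAI and ortholog-fraction matrices over a set of proteomes and
#' the shared/unique gene partition of the focal (first) genome, writing
#' TSV matrices, per-pair ortholog tables, partition lists and a manifest.
#'
#' @param config list (or YAML path) with `proteomes` (vector of protein
#'   FASTA paths, or list of [proteome()] objects), optional `outdir`, and
#'   optional `scoring` overrides (any [scoring_config()] argument).
#' @return (invisibly) the `comparison_matrices` plus the focal partition.
#' @export
run_compare <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$proteomes) || length(cfg$proteomes) < 2L)
    stop_config("run_compare config requires >= 2 proteomes")
  outdir <- cfg$outdir %||% "compare_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  cat("", file = logf)

  scoring <- do.call(scoring_config, cfg$scoring %||% list())
  prots <- lapply(cfg$proteomes, function(p)
    if (inherits(p, "proteome")) p else read_proteome(p))
  cm <- compare_genomes(prots, scoring)
  for (nm in names(cm$tables))
    log_msg("run_compare: ", nm, ": ", nrow(cm$tables[[nm]]$pairs),
            " ortholog pairs from ",
            length(prots[[1L]]$proteins) * length(prots[[2L]]$proteins),
            " alignments per direction", file = logf)

  write_matrix <- function(m, path)
    write_tsv(data.frame(genome = rownames(m), round(m),
                         check.names = FALSE), path)
  write_matrix(cm$aai, file.path(outdir, "aai.tsv"))
  write_matrix(cm$ortho_frac, file.path(outdir, "ortho_frac.tsv"))
  for (nm in names(cm$tables)) {
    tab <- cm$tables[[nm]]
    write_tsv(tab$pairs, file.path(outdir, paste0(
      "orthologs_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv")))
  }
  focal <- prots[[1L]]
  part <- gene_partition(focal, Filter(function(t)
    t$genome_a == focal$genome || t$genome_b == focal$genome, cm$tables))
  writeLines(part$shared, file.path(outdir, "shared_genes.txt"))
  writeLines(part$unique, file.path(outdir, "unique_genes.txt"))
  writeLines(sprintf("focal %s: %d shared, %d unique of %d proteins",
                     focal$genome, length(part$shared), length(part$unique),
                     length(focal$proteins)),
             file.path(outdir, "partition_report.txt"))
  write_manifest(outdir, list(
    genomes = cm$genomes,
    scoring = cfg$scoring %||% list(defaults = "BLOSUM62/11/1, lambda 0.267, K 0.041, E<=0.01, bit>=40, cov>=0.65"),
    focal = focal$genome))
  invisible(list(matrices = cm, partition = part, outdir = outdir))
}
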