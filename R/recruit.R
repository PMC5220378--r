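# Bin validation and scaffold recruitment on a trained map.

#' Percentile-based recruitment distance threshold
#'
#' The similarity cutoff is the maximum Euclidean distance between the
#' target bin's fragments and their best matching neurons after removing the
#' highest 2% of values. Removal drops the `ceiling(0.02 * n)` largest
#' distances; for fewer than 50 fragments nothing is dropped, so the cutoff
#' is the plain maximum (and the list can never be emptied).
#'
#' @param x either a numeric vector of BMU distances, or a fitted [esom()]
#'   (in which case `bin` selects the bin's fragments).
#' @param bin character vector of scaffold ids making up the bin (required
#'   when `x` is an `esom` fitted on a `feature_table`).
#' @param drop fraction of the largest distances to remove (default 0.02).
#' @return the threshold distance (scalar).
#' @export
recruitment_threshold <- function(x, bin = NULL, drop = 0.02) {
  d <- if (inherits(x, "esom")) {
    if (is.null(bin)) stop_config("bin scaffold ids required with an esom model")
    if (is.null(x$fragments))
      stop_config("model was not fitted on a feature_table; pass distances directly")
    x$bmu$distance[x$fragments$scaffold %in% bin]
  } else as.numeric(x)
  n <- length(d)
  if (n == 0L) stop_config("no bin fragments with a BMU distance")
  k <- if (n < 50L) 0L else min(ceiling(drop * n), n - 1L)
  d <- sort(d)
  d[n - k]
}

# neurons that are the BMU of at least one bin fragment
bin_neurons <- function(model, bin) {
  stopifnot(inherits(model, "esom"))
  if (is.null(model$fragments))
    stop_config("model must be fitted on a feature_table to locate bin fragments")
  idx <- model$fragments$scaffold %in% bin
  if (!any(idx)) stop_config("none of the bin scaffolds have fragments in the model")
  sort(unique(model$bmu$neuron[idx]))
}

#' Recruit candidate scaffolds into a bin
#'
#' For each candidate scaffold, the distance to the bin is the per-fragment
#' minimum Euclidean distance to any bin-associated neuron (a neuron that is
#' the BMU of at least one bin fragment), aggregated over the scaffold's
#' fragments by `aggregate` (default the minimum — the most generous
#' reading). A scaffold is recruited iff its distance is at most
#' `threshold`.
#'
#' @param model a fitted [esom()].
#' @param candidates a `feature_table` of candidate scaffolds projected into
#'   the model's feature space (see [transform_features()]).
#' @param bin character vector of bin scaffold ids.
#' @param threshold distance cutoff from [recruitment_threshold()].
#' @param aggregate `"min"` (default) or `"median"` over a scaffold's
#'   fragment distances.
#' @return an object of class `recruitment`: per-scaffold distances and the
#'   recruited/rejected partition.
#' @export
recruit <- function(model, candidates, bin, threshold,
                    aggregate = c("min", "median")) {
  stopifnot(inherits(model, "esom"), inherits(candidates, "feature_table"))
  aggregate <- match.arg(aggregate)
  neurons <- bin_neurons(model, bin)
  X <- candidates$combined
  d2 <- cross_dist2(X, model$codebook[neurons, , drop = FALSE])
  frag_d <- sqrt(pmax(rowMins(d2), 0))
  agg <- if (aggregate == "min") min else stats::median
  sc <- split(frag_d, candidates$fragments$scaffold)
  dist_by_scaffold <- vapply(sc, agg, numeric(1L))
  recruited <- names(dist_by_scaffold)[dist_by_scaffold <= threshold]
  rejected <- setdiff(names(dist_by_scaffold), recruited)
  structure(list(threshold = threshold, drop = 0.02,
                 distances = dist_by_scaffold,
                 recruited = recruited, rejected = rejected,
                 bin_neurons = neurons, aggregate = aggregate),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf("recruitment: threshold %.4f, %d recruited, %d rejected\n",
              x$threshold, length(x$recruited), length(x$rejected)))
  invisible(x)
}

#' Confirm recruited scaffolds by a second map analysis
#'
#' Retrains the SOM on the original fragments plus the recruited scaffolds'
#' fragments (fresh seed), labels each neuron by the majority bin membership
#' of the original fragments mapped to it, and confirms a recruited scaffold
#' iff the majority of its fragments land on bin-majority neurons. A single
#' confirmatory round is performed.
#'
#' @param train_features the `feature_table` the model was fitted on.
#' @param cand_features the candidates' `feature_table` (same space).
#' @param bin character vector of bin scaffold ids.
#' @param recruited scaffold ids recruited by [recruit()].
#' @param ... SOM settings passed to [esom()] (grid, epochs, topology...).
#' @param seed seed for the confirmatory retraining.
#' @return character vector of confirmed scaffold ids (subset of
#'   `recruited`).
#' @export
confirm <- function(train_features, cand_features, bin, recruited,
                    ..., seed = 2L) {
  stopifnot(inherits(train_features, "feature_table"),
            inherits(cand_features, "feature_table"))
  if (length(recruited) == 0L) return(character(0))
  keep <- cand_features$fragments$scaffold %in% recruited
  X <- rbind(train_features$combined, cand_features$combined[keep, , drop = FALSE])
  n_train <- nrow(train_features$combined)
  model2 <- esom(X, ..., seed = seed)
  bmu_all <- model2$bmu$neuron
  # label neurons by majority membership of the original fragments
  is_bin <- train_features$fragments$scaffold %in% bin
  nb <- tabulate(bmu_all[seq_len(n_train)][is_bin],
                 nbins = model2$rows * model2$cols)
  no <- tabulate(bmu_all[seq_len(n_train)][!is_bin],
                 nbins = model2$rows * model2$cols)
  bin_majority <- nb > no
  cand_bmu <- bmu_all[-seq_len(n_train)]
  cand_scaf <- cand_features$fragments$scaffold[keep]
  on_bin <- bin_majority[cand_bmu]
  frac <- vapply(split(on_bin, cand_scaf), mean, numeric(1L))
  names(frac)[frac > 0.5]
}
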