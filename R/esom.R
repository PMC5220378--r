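# Emergent self-organizing map: batch training with a Gaussian
# neighborhood on a (toroidal) grid, PCA codebook initialization.

#' Fit an emergent self-organizing map
#'
#' Batch SOM training: each epoch assigns every fragment to its best
#' matching unit (BMU), then replaces each neuron's weights by the
#' neighborhood-weighted mean of the assigned fragments. The Gaussian
#' neighborhood acts on grid distance (with wrap-around on the default
#' toroidal topology) and its radius decreases linearly from `radius0` to
#' `radius_final` across epochs. With radius 0 the update reduces to
#' Lloyd's k-means step. Training is deterministic given the seed.
#'
#' @param x a `feature_table` from [build_features()] or a numeric matrix
#'   (fragments x features).
#' @param rows,cols grid dimensions; if `NULL`, the number of neurons is
#'   chosen as about `5 * sqrt(n_fragments)` with the aspect ratio taken
#'   from the ratio of the first two principal-component standard
#'   deviations (an emergent-sized map).
#' @param epochs training passes over the data (default 10).
#' @param topology `"toroidal"` (default; borderless map) or `"planar"`.
#' @param init `"pca"` (default): the initial codebook spans a regular grid
#'   over the first two principal components (scores between +/- 2 sd);
#'   `"random"`: per-column draws from the empirical ranges.
#' @param radius0 initial neighborhood radius (default `max(rows, cols)/2`).
#' @param radius_final final radius (default 1).
#' @param seed integer seed (used by random init and as the model's stored
#'   seed).
#' @return an object of class `esom`: codebook, grid/config, per-fragment
#'   BMU assignments and distances, quantization-error trace.
#' @export
esom <- function(x, rows = NULL, cols = NULL, epochs = 10L,
                 topology = c("toroidal", "planar"),
                 init = c("pca", "random"),
                 radius0 = NULL, radius_final = 1, seed = 1L) {
  topology <- match.arg(topology)
  init <- match.arg(init)
  ft <- if (inherits(x, "feature_table")) x else NULL
  X <- if (is.null(ft)) as.matrix(x) else ft$combined
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop_config("need at least 2 fragments and 2 feature dimensions")
  if (epochs < 1L) stop_config("epochs must be >= 1")

  if (is.null(rows) || is.null(cols)) {
    dims <- choose_grid(X)
    rows <- rows %||% dims[1L]
    cols <- cols %||% dims[2L]
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 4L) stop_config("grid must have at least 4 neurons")
  radius0 <- radius0 %||% (max(rows, cols) / 2)
  if (radius0 < radius_final || radius_final < 0)
    stop_config("need radius0 >= radius_final >= 0")

  codebook <- init_codebook(X, rows, cols, init = init, seed = seed)
  gd <- grid_distances(rows, cols, topology)
  qe_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    r <- if (epochs == 1L) radius0 else
      radius0 + (radius_final - radius0) * (e - 1) / (epochs - 1)
    d2 <- cross_dist2(X, codebook)
    bmu_idx <- max.col(-d2, ties.method = "first")
    H <- if (r > 0) exp(-gd^2 / (2 * r^2)) else diag(nrow(codebook))
    Wgt <- H[bmu_idx, , drop = FALSE]           # fragments x neurons
    denom <- colSums(Wgt)
    num <- crossprod(Wgt, X)                    # neurons x D
    upd <- denom > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    qe_trace[e] <- mean(sqrt(pmax(rowMins(cross_dist2(X, codebook)), 0)))
  }
  d2 <- cross_dist2(X, codebook)
  bmu_idx <- max.col(-d2, ties.method = "first")
  bmu_dist <- sqrt(pmax(d2[cbind(seq_len(nrow(X)), bmu_idx)], 0))

  structure(list(
    codebook = codebook, rows = rows, cols = cols,
    topology = topology, init = init, epochs = as.integer(epochs),
    radius0 = radius0, radius_final = radius_final, seed = as.integer(seed),
    fragments = if (!is.null(ft)) ft$fragments else NULL,
    bmu = data.frame(neuron = bmu_idx, distance = bmu_dist),
    qe_trace = qe_trace,
    quantization_error = mean(bmu_dist)
  ), class = "esom")
}

choose_grid <- function(X) {
  n_neurons <- max(4, round(5 * sqrt(nrow(X))))
  ratio <- tryCatch({
    p <- prcomp(X, center = FALSE, scale. = FALSE, rank. = 2L)
    s <- p$sdev[1:2]
    if (s[2] > 0) min(max(s[1] / s[2], 1), 3) else 1
  }, error = function(e) 1)
  rows <- max(2L, round(sqrt(n_neurons / ratio)))
  cols <- max(2L, round(n_neurons / rows))
  c(rows, cols)
}

# squared Euclidean distances, rows of A vs rows of B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

rowMins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

# pairwise grid distances between neurons (row-major neuron order)
grid_distances <- function(rows, cols, topology) {
  idx <- seq_len(rows * cols) - 1L
  r <- idx %/% cols
  c <- idx %% cols
  dr <- abs(outer(r, r, "-"))
  dc <- abs(outer(c, c, "-"))
  if (topology == "toroidal") {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  sqrt(dr^2 + dc^2)
}

#' Initialize a SOM codebook
#'
#' PCA initialization lays the codebook on a regular grid spanning +/- 2
#' standard deviations of the scores along the first two principal
#' components; it is deterministic. If the feature covariance has rank < 2
#' the initializer falls back to seeded random draws from the per-column
#' empirical ranges, with a warning.
#'
#' @param X numeric matrix (fragments x features).
#' @param rows,cols grid dimensions.
#' @param init `"pca"` or `"random"`.
#' @param seed seed for random init.
#' @return (rows*cols) x D codebook matrix, neuron order row-major.
#' @export
init_codebook <- function(X, rows, cols, init = c("pca", "random"), seed = 1L) {
  init <- match.arg(init)
  if (init == "pca") {
    p <- prcomp(X, center = TRUE, scale. = FALSE)
    if (length(p$sdev) < 2L || p$sdev[2L] <= 1e-12 * p$sdev[1L]) {
      warning("degenerate covariance (rank < 2): falling back to random init")
      return(init_codebook(X, rows, cols, init = "random", seed = seed))
    }
    s1 <- seq(-2, 2, length.out = rows) * p$sdev[1L]
    s2 <- seq(-2, 2, length.out = cols) * p$sdev[2L]
    mu <- colMeans(X)
    cb <- matrix(0, rows * cols, ncol(X))
    k <- 1L
    for (i in seq_len(rows)) for (j in seq_len(cols)) {
      cb[k, ] <- mu + s1[i] * p$rotation[, 1L] + s2[j] * p$rotation[, 2L]
      k <- k + 1L
    }
    cb
  } else {
    with_seed(seed, {
      lo <- apply(X, 2L, min)
      hi <- apply(X, 2L, max)
      matrix(runif(rows * cols * ncol(X)), rows * cols, ncol(X)) %*%
        diag(hi - lo, ncol(X)) + rep(lo, each = rows * cols)
    })
  }
}

#' Best matching unit for one or more feature vectors
#'
#' @param model a fitted [esom()].
#' @param x numeric vector (length D) or matrix (n x D).
#' @return data.frame with `neuron` (1-based index, ties broken by lowest
#'   index) and `distance` (Euclidean).
#' @export
bmu <- function(model, x) {
  stopifnot(inherits(model, "esom"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model$codebook))
    stop_format("feature dimension mismatch: got ", ncol(x),
                ", codebook has ", ncol(model$codebook))
  d2 <- cross_dist2(as.matrix(x), model$codebook)
  idx <- max.col(-d2, ties.method = "first")
  data.frame(neuron = idx,
             distance = sqrt(pmax(d2[cbind(seq_len(nrow(x)), idx)], 0)))
}

#' @export
predict.esom <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$combined else
    as.matrix(newdata)
  bmu(object, X)
}

#' U-matrix of a fitted SOM
#'
#' Per neuron, the mean Euclidean distance from its weight vector to its
#' grid neighbors (8-neighborhood, with wrap-around on a toroidal map).
#' High values mark cluster boundaries.
#'
#' @param model a fitted [esom()].
#' @return numeric matrix of shape (rows, cols).
#' @export
umatrix <- function(model) {
  stopifnot(inherits(model, "esom"))
  rows <- model$rows; cols <- model$cols
  cb <- model$codebook
  toroid <- model$topology == "toroidal"
  um <- matrix(0, rows, cols)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    me <- (r - 1L) * cols + c
    acc <- 0; nn <- 0L
    for (k in seq_len(nrow(offs))) {
      rr <- r - 1L + offs$dr[k]; cc <- c - 1L + offs$dc[k]
      if (toroid) {
        rr <- rr %% rows; cc <- cc %% cols
      } else if (rr < 0L || rr >= rows || cc < 0L || cc >= cols) next
      other <- rr * cols + cc + 1L
      acc <- acc + sqrt(sum((cb[me, ] - cb[other, ])^2))
      nn <- nn + 1L
    }
    um[r, c] <- if (nn > 0L) acc / nn else 0
  }
  um
}

#' @export
print.esom <- function(x, ...) {
  cat(sprintf("esom: %d x %d %s grid, %d epochs, %s init\n",
              x$rows, x$cols, x$topology, x$epochs, x$init))
  cat(sprintf("  %d fragments, quantization error %.4f\n",
              nrow(x$bmu), x$quantization_error))
  invisible(x)
}

#' @export
summary.esom <- function(object, ...) {
  occ <- tabulate(object$bmu$neuron, nbins = object$rows * object$cols)
  cat(sprintf("esom %d x %d (%s), %d neurons, %d fragments\n",
              object$rows, object$cols, object$topology,
              object$rows * object$cols, nrow(object$bmu)))
  cat(sprintf("  occupied neurons: %d (%.0f%%)\n", sum(occ > 0),
              100 * mean(occ > 0)))
  cat(sprintf("  quantization error: %.4f (epoch trace: %s)\n",
              object$quantization_error,
              paste(sprintf("%.3f", object$qe_trace), collapse = " ")))
  invisible(object)
}

#' Plot the U-matrix with fragments at their BMU grid positions
#'
#' @param x a fitted [esom()].
#' @param labels optional per-fragment labels (e.g. bin membership) used to
#'   color the overlaid points.
#' @param ... passed to [graphics::image()].
#' @method plot esom
#' @export
plot.esom <- function(x, labels = NULL, ...) {
  um <- umatrix(x)
  image(seq_len(x$cols), seq_len(x$rows), t(um),
        col = gray(seq(1, 0, length.out = 64)),
        xlab = "column", ylab = "row", main = "ESOM U-matrix", ...)
  if (!is.null(labels)) {
    labs <- as.factor(labels)
    pal <- colorRampPalette(c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3",
                              "#FF7F00", "#FFFF33"))(nlevels(labs))
    nr <- (x$bmu$neuron - 1L) %/% x$cols + 1L
    nc <- (x$bmu$neuron - 1L) %% x$cols + 1L
    xy <- with_seed(0, cbind(jitter(nc, 0.4), jitter(nr, 0.4)))
    points(xy[, 1L], xy[, 2L], col = pal[as.integer(labs)],
           pch = 16, cex = 0.6)
    legend("topright", legend = levels(labs), col = pal, pch = 16,
           cex = 0.7, bg = "white")
  }
  invisible(x)
}
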