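#' Train a self-organizing map on chemoactivity profiles
#'
#' Batch-style Kohonen SOM on a rectangular grid, tolerant of missing
#' values: distances are squared Euclidean over observed entries only,
#' normalized by the number observed, and codebook updates use only the
#' observed components of each sample (every node of a winning neighborhood
#' is pulled on all components for which any weighted sample is observed).
#'
#' Each epoch finds every profile's best-matching unit, then moves every
#' codebook toward the neighborhood-weighted mean of its assigned samples:
#' `c <- (1 - lr) * c + lr * wmean`. The Gaussian neighborhood radius decays
#' linearly from `max(rows, cols)/2` to 1 and the learning rate from 0.5 to
#' 0.01 over the epochs. Codebooks are initialized from randomly drawn data
#' rows (missing entries filled with the panel mean profile). Training is
#' fully reproducible for a fixed seed.
#'
#' @param profiles a normalized [ChemoProfileSet-class]
#' @param config a [RunConfig-class]; grid dims, epochs and seed are taken
#'   from it unless overridden
#' @param rows,cols,epochs,seed optional overrides of the config values
#' @return a [SOMModel-class] with the per-epoch quantization-error log
#' @export
trainSOM <- function(profiles, config = runConfig(), rows = config@somRows,
                     cols = config@somCols, epochs = config@somEpochs,
                     seed = config@rngSeed) {
  stopifnot(is(profiles, "ChemoProfileSet"))
  X <- chemoValues(profiles)
  if (nrow(X) < 1L) stop("need at least one profile to train")
  if (any(is.infinite(X))) stop("non-finite chemoactivity values")
  if (any(rowSums(!is.na(X)) == 0L)) stop("profile with all entries missing")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("grid dimensions must be >= 1")
  K <- rows * cols
  p <- ncol(X)
  colMeanProf <- colMeans(X, na.rm = TRUE)
  colMeanProf[is.na(colMeanProf)] <- 0

  # grid coordinates of node k (row-major, 0-based)
  gr <- (seq_len(K) - 1L) %/% cols
  gc <- (seq_len(K) - 1L) %% cols
  grid2 <- outer(gr, gr, function(a, b) (a - b)^2) +
    outer(gc, gc, function(a, b) (a - b)^2)

  lr0 <- 0.5; lr1 <- 0.01
  # radius ends at 0.5: a Gaussian of sd 0.5 leaves neighbors at grid
  # distance 1 with weight e^-2, so late epochs fine-tune near-BMU-only
  # and the quantization error settles instead of plateauing high
  r0 <- max(rows, cols) / 2; r1 <- 0.5

  C <- .withSeed(seed, {
    idx <- sample.int(nrow(X), K, replace = TRUE)
    C0 <- X[idx, , drop = FALSE]
    C0[is.na(C0)] <- matrix(colMeanProf, K, p, byrow = TRUE)[is.na(C0)]
    C0
  })
  dimnames(C) <- list(NULL, colnames(X))

  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  qeLog <- numeric(epochs)
  for (e in seq_len(epochs)) {
    frac <- if (epochs > 1L) (e - 1) / (epochs - 1) else 0
    lr <- lr0 + frac * (lr1 - lr0)
    rad <- r0 + frac * (r1 - r0)
    d2 <- .maskedDist2(X, C)
    bmu <- max.col(-d2, ties.method = "first")
    qeLog[e] <- mean(sqrt(d2[cbind(seq_len(nrow(X)), bmu)]))
    # Gaussian neighborhood weight of node k for a sample won by node bmu
    Hn <- exp(-grid2 / (2 * rad^2))            # K x K
    W <- Hn[, bmu, drop = FALSE]               # K x n
    num <- W %*% X0                            # weighted sums, masked
    den <- W %*% M                             # weighted observation counts
    upd <- den > 0
    target <- C
    target[upd] <- (num / den)[upd]
    C <- (1 - lr) * C + lr * target
  }
  new("SOMModel", rows = rows, cols = cols, codebook = C,
      trainParams = list(epochs = as.integer(epochs), lr0 = lr0, lr1 = lr1,
                         radius0 = r0, radius1 = r1),
      seed = as.integer(seed), qeLog = qeLog)
}

#' Best-matching node of a chemoactivity profile
#'
#' Masked Euclidean distance (normalized by observed-entry count) to every
#' codebook; ties break deterministically to the lowest node index.
#'
#' @param model a [SOMModel-class]
#' @param profile numeric vector over the model's panel (NA = missing), or a
#'   [ChemoProfileSet-class] (one node per compound)
#' @return 0-based node index (vector for a set)
#' @export
assignNode <- function(model, profile) {
  stopifnot(is(model, "SOMModel"))
  X <- if (is(profile, "ChemoProfileSet")) chemoValues(profile)
  else matrix(profile, nrow = 1L,
              dimnames = list(NULL, cellIds(model)))
  if (ncol(X) != ncol(codebook(model)))
    stop("profile length does not match the model's panel")
  if (any(rowSums(!is.na(X)) == 0L)) stop("all-missing profile")
  d2 <- .maskedDist2(X, codebook(model))
  idx <- max.col(-d2, ties.method = "first") - 1L
  if (nrow(X) == 1L) idx[1L] else stats::setNames(idx, rownames(X))
}

#' Codebook ("SOM GI50") profile of a node
#' @param model a [SOMModel-class]
#' @param node 0-based node index
#' @return named numeric vector over the panel
#' @export
codebookProfile <- function(model, node) {
  stopifnot(is(model, "SOMModel"))
  if (node < 0L || node >= nNodes(model))
    stop("node index out of range [0, ", nNodes(model) - 1L, "]")
  codebook(model)[node + 1L, ]
}

#' Project per-node scores onto the map grid
#'
#' @param model a [SOMModel-class]
#' @param nodeScores named numeric vector; names are 0-based node indices.
#'   Nodes without a score become NA.
#' @return rows x cols numeric matrix; cell (r, c) holds the score of node
#'   `r * cols + c` (0-based r, c)
#' @export
projectScores <- function(model, nodeScores) {
  stopifnot(is(model, "SOMModel"))
  g <- matrix(NA_real_, model@rows, model@cols)
  if (length(nodeScores)) {
    idx <- as.integer(names(nodeScores))
    if (any(is.na(idx) | idx < 0L | idx >= nNodes(model)))
      stop("nodeScores names must be 0-based node indices")
    g[cbind(idx %/% model@cols + 1L, idx %% model@cols + 1L)] <- nodeScores
  }
  g
}

#' Mean quantization error of profiles under a trained map
#' @param model a [SOMModel-class]
#' @param profiles a [ChemoProfileSet-class] over the same panel
#' @return mean over compounds of masked distance to the best-matching unit
#' @export
quantizationError <- function(model, profiles) {
  stopifnot(is(model, "SOMModel"), is(profiles, "ChemoProfileSet"))
  X <- chemoValues(profiles)
  d2 <- .maskedDist2(X, codebook(model))
  mean(sqrt(apply(d2, 1L, min)))
}
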