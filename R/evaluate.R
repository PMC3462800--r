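# Fisher linear discriminant: direction w = pinv(Sw) (mu1 - mu0), decision
# at the midpoint of the projected class means, equal priors. The
# pseudo-inverse keeps the criterion defined when genes outnumber cells
# (singular pooled covariance) and is deterministic.
.fisherLDA <- function(Xtr, ytr) {
  mu1 <- rowMeans(Xtr[, ytr, drop = FALSE])
  mu0 <- rowMeans(Xtr[, !ytr, drop = FALSE])
  X1 <- Xtr[, ytr, drop = FALSE] - mu1
  X0 <- Xtr[, !ytr, drop = FALSE] - mu0
  n <- ncol(Xtr)
  Sw <- (X1 %*% t(X1) + X0 %*% t(X0)) / max(n - 2L, 1L)
  # Tiny ridge, then an exact solve: the ridged pooled covariance is
  # positive definite even for p >> n, and unlike a pseudo-inverse with a
  # relative tolerance it keeps directions whose within-class variance
  # vanishes — exactly the ones Fisher's criterion rewards most. For
  # well-conditioned problems the ridge is numerically invisible and the
  # result matches the pseudo-inverse direction.
  md <- mean(diag(Sw))
  d <- mu1 - mu0
  w <- if (md > 0) solve(Sw + diag(1e-8 * md, nrow(Sw)), d)
  else MASS::ginv(Sw) %*% d
  w <- matrix(w, ncol = 1L)
  list(w = w, cut = as.numeric(crossprod(w, (mu1 + mu0) / 2)))
}

.fisherPredict <- function(fit, X) as.numeric(crossprod(fit$w, X)) > fit$cut

# Stratified fold labels keyed by sorted cell id: cells are ordered by
# class then id, permuted within class under the seed, concatenated, and
# dealt fold labels 1..k cyclically. Column order of the input therefore
# never changes the partition, and k = n yields exact leave-one-out.
.foldAssign <- function(cells, y, k, seed) {
  ord <- order(!y, cells)  # sensitive block first, each sorted by id
  .withSeed(seed, {
    idx1 <- which(y[ord]); idx0 <- which(!y[ord])
    perm <- c(sample(idx1), sample(idx0))
  })
  folds <- integer(length(cells))
  folds[ord[perm]] <- rep_len(seq_len(k), length(cells))
  names(folds) <- cells
  folds
}

#' Cross-validated Fisher LDA accuracy
#'
#' Stratified k-fold cross-validation of a Fisher linear discriminant
#' predicting the sensitive/insensitive label from gene expression. Folds
#' are assigned from the seed and the sorted cell ids, so the result is
#' invariant to column order. Missing expression entries are mean-imputed
#' per gene using training-fold means. The returned consensus accuracy is
#' the fraction of all cells predicted correctly when held out.
#'
#' @param features numeric matrix, genes x cells (NA allowed)
#' @param labels logical (TRUE = sensitive) or character
#'   ("sensitive"/"insensitive") per cell
#' @param k number of folds (k = ncol gives leave-one-out)
#' @param seed fold-assignment seed
#' @return consensus accuracy in [0, 1]
#' @export
ldaCvAccuracy <- function(features, labels, k = 5L, seed = 1L) {
  features <- as.matrix(features)
  y <- if (is.character(labels)) labels == "sensitive" else as.logical(labels)
  n <- ncol(features)
  stopifnot(length(y) == n, k >= 2L, k <= n)
  cells <- colnames(features)
  if (is.null(cells)) cells <- sprintf("cell%03d", seq_len(n))
  if (sum(y) < 1L || sum(!y) < 1L) stop("both classes must be present")
  folds <- NULL
  for (attempt in seq_len(10L)) {
    f <- .foldAssign(cells, y, k, seed + (attempt - 1L) * 1000L)
    ok <- all(vapply(seq_len(k), function(t) {
      tr <- f != t
      !any(f == t) || (any(y[tr]) && any(!y[tr]))
    }, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds))
    stop("could not build folds with both classes in every training set")
  correct <- logical(n)
  for (t in seq_len(k)) {
    te <- which(folds == t)
    if (!length(te)) next
    tr <- which(folds != t)
    mtr <- rowMeans(features[, tr, drop = FALSE], na.rm = TRUE)
    Xtr <- .imputeRows(features[, tr, drop = FALSE], mtr)
    Xte <- .imputeRows(features[, te, drop = FALSE], mtr)
    fit <- .fisherLDA(Xtr, y[tr])
    correct[te] <- .fisherPredict(fit, Xte) == y[te]
  }
  mean(correct)
}

#' Conventional correlation-based gene selection (pathway-free baseline)
#'
#' Ranks every measured gene by the significance of its Pearson correlation
#' with the chemoactivity profile and cuts either at a p-value threshold
#' (`mode = "alpha"`) or at the top percentile of |r| (`mode =
#' "percentile"`, `ceiling` count, boundary ties included).
#'
#' @param expr an [ExpressionMatrix-class]
#' @param chemoProfile named numeric vector over the panel
#' @param mode `"alpha"` or `"percentile"`
#' @param value the threshold: alpha level or percentile
#' @return data.frame (gene, r, p), ordered by r ascending
#' @export
conventionalSelection <- function(expr, chemoProfile,
                                  mode = c("alpha", "percentile"),
                                  value = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is(expr, "ExpressionMatrix"))
  E <- exprValues(expr)
  rn <- .corAgainstProfile(E, chemoProfile)
  r <- rn$r; n <- rn$n
  p <- .corPValue(r, n)
  genes <- rownames(E)
  keep <- if (mode == "alpha") {
    !is.na(p) & p < value
  } else {
    def <- which(!is.na(r))
    k <- ceiling(value / 100 * length(def))
    a <- abs(r[def])
    cut <- sort(a, decreasing = TRUE)[k]
    !is.na(r) & abs(r) >= cut
  }
  out <- data.frame(gene = genes[keep], r = r[keep], p = p[keep])
  out[order(out$r, out$gene), , drop = FALSE]
}

#' Compare pathway-derived and conventional gene selection by LDA accuracy
#'
#' For each requested SOM node, builds four discriminating-gene arms —
#' pathway-derived and conventional, each trimmed and untrimmed — and
#' scores each by cross-validated LDA accuracy with identical fold seeds
#' (paired comparison). Untrimmed arms use all cells with defined
#' chemoactivity; trimmed arms use the trimmed cells and labels. Units
#' whose pool empties or whose trim fails are skipped and counted.
#'
#' @param expr filtered [ExpressionMatrix-class] (pathway arm)
#' @param pathways filtered [PathwayCollection-class]
#' @param model trained [SOMModel-class]
#' @param hTable [HScoreTable-class] for the model
#' @param nodes integer vector of 0-based node indices to evaluate
#' @param config a [RunConfig-class]
#' @param seed base seed; each node derives its own fold seed from it
#' @param exprAll [ExpressionMatrix-class] the conventional arm selects
#'   from; defaults to `expr`. Pass the unfiltered matrix so the baseline
#'   ignores pathway structure entirely, as it is defined to.
#' @return list: `summary` (data.frame with one row per method x trimming:
#'   mean/sd accuracy, gene count, cell count), `units` (per-node detail),
#'   `n_failed`
#' @export
methodComparison <- function(expr, pathways, model, hTable, nodes,
                             config = runConfig(), seed = config@rngSeed,
                             exprAll = expr) {
  rows <- list()
  nFail <- 0L
  for (nd in nodes) {
    prof <- codebookProfile(model, nd)
    labAll <- ifelse(prof > 0, "sensitive", "insensitive")
    foldSeed <- seed + as.integer(nd)
    pool <- candidatePool(nd, hTable, expr, prof, pathways, config)
    conv <- conventionalSelection(exprAll, prof, config@conventionalMode,
                                  config@conventionalValue)
    unit <- list()
    okUnit <- TRUE
    for (m in c("pathway", "conventional")) {
      po <- if (m == "pathway") pool else conv
      armExpr <- if (m == "pathway") expr else exprAll
      E <- exprValues(armExpr)
      if (nrow(po) < 2L) { okUnit <- FALSE; break }
      accU <- tryCatch(
        ldaCvAccuracy(E[po$gene, , drop = FALSE], labAll,
                      k = config@ldaFolds, seed = foldSeed),
        error = function(e) NA_real_)
      ds <- trimDiscriminant(po, armExpr, prof, config)
      if (!ds@converged || length(ds@genes) < 2L) { okUnit <- FALSE; break }
      accT <- tryCatch(
        ldaCvAccuracy(E[ds@genes, ds@cells, drop = FALSE], ds@cellClass,
                      k = min(config@ldaFolds, length(ds@cells)),
                      seed = foldSeed),
        error = function(e) NA_real_)
      if (is.na(accU) || is.na(accT)) { okUnit <- FALSE; break }
      unit[[paste0(m, "_untrimmed")]] <-
        c(acc = accU, genes = nrow(po), cells = ncol(E))
      unit[[paste0(m, "_trimmed")]] <-
        c(acc = accT, genes = length(ds@genes), cells = length(ds@cells))
    }
    if (!okUnit) { nFail <- nFail + 1L; next }
    rows[[as.character(nd)]] <- unit
  }
  arms <- c("pathway_trimmed", "pathway_untrimmed",
            "conventional_trimmed", "conventional_untrimmed")
  summ <- do.call(rbind, lapply(arms, function(a) {
    vals <- t(vapply(rows, `[[`, numeric(3), a))
    data.frame(
      method = sub("_.*", "", a), trimming = sub(".*_", "", a),
      mean_accuracy = mean(vals[, "acc"]), sd_accuracy = stats::sd(vals[, "acc"]),
      mean_genes = mean(vals[, "genes"]), sd_genes = stats::sd(vals[, "genes"]),
      mean_cells = mean(vals[, "cells"]), sd_cells = stats::sd(vals[, "cells"]))
  }))
  list(summary = summ, units = rows, n_failed = nFail)
}

#' Concordance of top pathways: raw compound profiles vs their SOM node
#'
#' Samples nodes that have assigned compounds; from each, samples raw
#' compound chemoactivity profiles (with replacement when a node holds
#' fewer members than requested). For every sampled raw profile the
#' top-percentile pathway set is computed and compared with the node
#' codebook's top set; the overlap fraction is the share of the raw
#' profile's top pathways also present in the node's top set.
#'
#' @param model trained [SOMModel-class]
#' @param expr filtered [ExpressionMatrix-class]
#' @param chemo normalized [ChemoProfileSet-class] (raw compound profiles)
#' @param assignments named integer vector compound -> node
#'   (from [assignNode()])
#' @param pathways filtered [PathwayCollection-class]
#' @param config a [RunConfig-class]
#' @param nNodesSample number of nodes to sample (default 100)
#' @param membersPerNode raw profiles sampled per node (default 20)
#' @param seed sampling seed
#' @return list: `fractions`, `mean`, `sd`
#' @export
pathwayOverlapConcordance <- function(model, expr, chemo, assignments,
                                      pathways, config = runConfig(),
                                      nNodesSample = 100L,
                                      membersPerNode = 20L,
                                      seed = config@rngSeed) {
  occupied <- unique(assignments)
  if (!length(occupied)) stop("no nodes have assigned compounds")
  V <- chemoValues(chemo)
  fractions <- numeric(0)
  .withSeed(seed, {
    nodesPick <- sample(occupied, nNodesSample, replace = TRUE)
    for (nd in nodesPick) {
      members <- names(assignments)[assignments == nd]
      picks <- sample(members, membersPerNode,
                      replace = membersPerNode > length(members))
      nodeTop <- {
        corr <- geneNodeCorrelations(expr, codebook(model)[nd + 1L, ,
                                                           drop = FALSE])
        tab <- hScoreTable(corr, pathways)
        topPercentilePathways(tab, hRecords(tab)$node[1L],
                              config@hTopPercentile)
      }
      for (cp in picks) {
        corr <- geneNodeCorrelations(
          expr, matrix(V[cp, ], nrow = 1L,
                       dimnames = list(cp, colnames(V))))
        tab <- hScoreTable(corr, pathways)
        rawTop <- topPercentilePathways(tab, hRecords(tab)$node[1L],
                                        config@hTopPercentile)
        fractions <- c(fractions,
                       if (length(rawTop))
                         length(intersect(rawTop, nodeTop)) / length(rawTop)
                       else 0)
      }
    }
  })
  list(fractions = fractions, mean = mean(fractions),
       sd = stats::sd(fractions))
}

#' Effect of white-noise degradation on the discriminating-gene count
#'
#' Adds i.i.d. Gaussian noise to the expression matrix, bisecting the noise
#' sd until the mean per-gene Pearson correlation between original and
#' degraded values reaches `target` (within `tol`). One noise pattern is
#' drawn once and scaled, so the correlation is monotone in sigma and the
#' bisection converges deterministically. The candidate pool and trim are
#' then re-run on the degraded data and the surviving gene count compared
#' with the baseline. The candidate pool reliably shrinks (noise attenuates
#' every correlation, pushing marginal genes below the significance gate);
#' the post-trim count can move either way on small panels because the trim
#' also drops noisier cells, so both ratios are reported.
#'
#' @param expr filtered [ExpressionMatrix-class]
#' @param target target mean original-vs-degraded correlation (e.g. 0.6)
#' @param node 0-based node index of the reference profile
#' @param hTable [HScoreTable-class] computed on the original data
#' @param pathways filtered [PathwayCollection-class]
#' @param chemoProfile reference chemoactivity profile over the panel
#' @param config a [RunConfig-class]
#' @param seed noise-pattern seed
#' @param baseline optional pre-computed baseline [DiscriminantSet-class]
#' @param tol tolerance on the achieved mean correlation (default 0.02)
#' @return list: `expr` (degraded matrix), `sigma`, `achieved` (mean
#'   correlation), `ratio` (degraded / baseline trimmed gene count),
#'   `pool_ratio` (degraded / baseline candidate pool size),
#'   `baseline_genes`, `degraded_genes`, `baseline_pool`, `degraded_pool`
#' @export
noiseDegradation <- function(expr, target, node, hTable, pathways,
                             chemoProfile, config = runConfig(),
                             seed = config@rngSeed, baseline = NULL,
                             tol = 0.02) {
  stopifnot(target > 0, target <= 1)
  E <- exprValues(expr)
  Z <- .withSeed(seed, matrix(stats::rnorm(length(E)), nrow(E), ncol(E)))
  Z[is.na(E)] <- NA
  meanCor <- function(sigma) {
    D <- E + sigma * Z
    mean(vapply(seq_len(nrow(E)), function(i)
      .pearsonPair(E[i, ], D[i, ])$r, numeric(1)), na.rm = TRUE)
  }
  lo <- 0; hi <- 1
  while (meanCor(hi) > target) {
    hi <- hi * 2
    if (hi > 1e6) stop("target correlation unreachable; achieved ",
                       signif(meanCor(1e6), 3), " at sigma = 1e6")
  }
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (meanCor(mid) > target) lo <- mid else hi <- mid
    if (abs(meanCor(mid) - target) <= tol) { lo <- hi <- mid; break }
  }
  sigma <- (lo + hi) / 2
  achieved <- meanCor(sigma)
  if (abs(achieved - target) > tol)
    stop("bisection did not reach target; achieved ", signif(achieved, 3))
  D <- ExpressionMatrix(E + sigma * Z)
  pool0 <- candidatePool(node, hTable, expr, chemoProfile, pathways, config)
  if (is.null(baseline))
    baseline <- trimDiscriminant(pool0, expr, chemoProfile, config)
  poolD <- candidatePool(node, hTable, D, chemoProfile, pathways, config)
  setD <- trimDiscriminant(poolD, D, chemoProfile, config)
  nb <- length(baseline@genes)
  list(expr = D, sigma = sigma, achieved = achieved,
       ratio = if (nb) length(setD@genes) / nb else NA_real_,
       pool_ratio = if (nrow(pool0)) nrow(poolD) / nrow(pool0) else NA_real_,
       baseline_genes = nb, degraded_genes = length(setD@genes),
       baseline_pool = nrow(pool0), degraded_pool = nrow(poolD))
}
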