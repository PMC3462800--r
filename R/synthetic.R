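#' Generate an NCI60-like synthetic panel with planted ground truth
#'
#' Emulates the structure of a tumor-cell screening panel: compound
#' clusters share a base chemoactivity profile (+1 on a drawn
#' sensitive-cell subset, -1 elsewhere) plus per-compound Gaussian noise,
#' and each cluster has one planted pathway whose member genes carry
#' expression shifted between sensitive and insensitive cells. Half of each
#' planted pathway's genes associate positively with sensitivity, half
#' negatively, so all four over/under x sensitive/insensitive response
#' classes are populated. Remaining genes are i.i.d. standard-normal
#' background; remaining pathways draw members from the background genes.
#'
#' A planted gene is `g = s * effectSize / sqrt(2) * base + N(0, noiseSd^2)`
#' (with `s = +/-1` and `base` the cluster's +/-1 sensitivity profile), so
#' its expected correlation with the base profile is
#' `effectSize / sqrt(effectSize^2 + 2 * noiseSd^2)`.
#'
#' Entries of both matrices are masked missing independently at
#' `missingRate`. Output is byte-deterministic for a fixed seed.
#'
#' @param nCells panel size (default 59, the full screening complement)
#' @param nGenes total gene count (default 600)
#' @param nPathways total pathway count (default 40), `>= nClusters`
#' @param pathwaySizeRange min/max member genes per pathway (default 8-25)
#' @param nClusters compound clusters, one planted pathway each (default 4)
#' @param compoundsPerCluster compounds replicating each base profile
#' @param effectSize planted expression shift, in noise-sd-free units
#'   (default 1.5)
#' @param noiseSd sd of the chemoactivity and planted-expression noise
#'   (default 0.5)
#' @param missingRate independent missingness rate of matrix entries
#' @param seed RNG seed
#' @return list: `expr` ([ExpressionMatrix-class]), `chemo` (raw
#'   [ChemoProfileSet-class]), `pathways` ([PathwayCollection-class]),
#'   `truth` (list: plantedPathways, sensitiveCells, geneEffect,
#'   clusterOf, baseProfiles, noiseSd, effectSize, seed)
#' @export
generatePanel <- function(nCells = 59L, nGenes = 600L, nPathways = 40L,
                          pathwaySizeRange = c(8L, 25L), nClusters = 4L,
                          compoundsPerCluster = 10L, effectSize = 1.5,
                          noiseSd = 0.5, missingRate = 0.02, seed = 1L) {
  if (nPathways < nClusters) stop("need at least one pathway per cluster")
  if (pathwaySizeRange[1L] < 2L) stop("pathway sizes must be >= 2")
  if (nCells < 12L) stop("panel too small for a non-trivial split")
  cells <- sprintf("CL%02d", seq_len(nCells))
  genes <- sprintf("G%04d", seq_len(nGenes))
  .withSeed(seed, {
    sizes <- sample(seq(pathwaySizeRange[1L], pathwaySizeRange[2L]),
                    nPathways, replace = TRUE)
    if (sum(sizes[seq_len(nClusters)]) > nGenes / 2)
      stop("planted pathways would consume more than half the genes")
    # planted pathways take dedicated leading genes; background pathways
    # sample from the remaining background pool
    ptr <- 0L
    sets <- vector("list", nPathways)
    names(sets) <- sprintf("PW%02d", seq_len(nPathways))
    planted <- names(sets)[seq_len(nClusters)]
    for (c_ in seq_len(nClusters)) {
      sets[[c_]] <- genes[ptr + seq_len(sizes[c_])]
      ptr <- ptr + sizes[c_]
    }
    background <- genes[(ptr + 1L):nGenes]
    if (nPathways > nClusters)
      for (j in seq(nClusters + 1L, nPathways))
        sets[[j]] <- sample(background, sizes[j])
    pathways <- PathwayCollection(sets, description = "synthetic gene set",
                                  source = "synthetic")

    # sensitivity splits and base profiles
    sensitiveCells <- lapply(seq_len(nClusters), function(c_)
      sort(sample(cells, sample(20:(nCells - 20L), 1L))))
    names(sensitiveCells) <- planted
    base <- t(vapply(sensitiveCells, function(sc)
      ifelse(cells %in% sc, 1, -1), numeric(nCells)))
    colnames(base) <- cells

    # chemoactivity: cluster base + compound noise
    nCpd <- nClusters * compoundsPerCluster
    clusterOf <- rep(seq_len(nClusters), each = compoundsPerCluster)
    cpd <- sprintf("CPD_%02d_%02d", clusterOf,
                   sequence(rep(compoundsPerCluster, nClusters)))
    C <- base[clusterOf, , drop = FALSE] +
      matrix(stats::rnorm(nCpd * nCells, sd = noiseSd), nCpd, nCells)
    dimnames(C) <- list(cpd, cells)

    # expression: planted signal + noise, background standard normal
    E <- matrix(stats::rnorm(nGenes * nCells), nGenes, nCells,
                dimnames = list(genes, cells))
    geneEffect <- stats::setNames(rep(0, nGenes), genes)
    a <- effectSize / sqrt(2)
    for (c_ in seq_len(nClusters)) {
      mg <- sets[[c_]]
      sgn <- rep(c(1, -1), length.out = length(mg))
      E[mg, ] <- sgn %o% base[c_, ] * a +
        matrix(stats::rnorm(length(mg) * nCells, sd = noiseSd),
               length(mg), nCells)
      geneEffect[mg] <- sgn * effectSize
    }

    if (missingRate > 0) {
      E[stats::runif(length(E)) < missingRate] <- NA
      C[stats::runif(length(C)) < missingRate] <- NA
    }

    list(expr = ExpressionMatrix(E), chemo = ChemoProfileSet(C),
         pathways = pathways,
         truth = list(plantedPathways = stats::setNames(planted,
                                                        seq_len(nClusters)),
                      sensitiveCells = sensitiveCells,
                      geneEffect = geneEffect,
                      clusterOf = stats::setNames(clusterOf, cpd),
                      baseProfiles = base, noiseSd = noiseSd,
                      effectSize = effectSize, seed = seed))
  })
}

#' Degrade an expression matrix with white noise
#'
#' Adds i.i.d. `N(0, sigma^2)` to every non-missing entry; masked entries
#' stay masked. `sigma = 0` returns an identical matrix.
#'
#' @param expr an [ExpressionMatrix-class]
#' @param sigma noise standard deviation, `>= 0`
#' @param seed RNG seed
#' @return a degraded [ExpressionMatrix-class]
#' @export
degradeExpression <- function(expr, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  E <- exprValues(expr)
  if (sigma > 0) {
    Z <- .withSeed(seed, matrix(stats::rnorm(length(E), sd = sigma),
                                nrow(E), ncol(E)))
    E <- E + ifelse(is.na(E), 0, Z)
  }
  ExpressionMatrix(E)
}
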