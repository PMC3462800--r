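#' Candidate discriminating genes from top-scoring pathways
#'
#' Collects the union of member genes of the pathways in the top percentile
#' of signed H-scores at a node, correlates each with the reference
#' chemoactivity profile (codebook or raw compound profile), converts r to a
#' two-sided p-value via `t = r * sqrt((n - 2) / (1 - r^2))`, and keeps the
#' genes significant at `corrAlpha`.
#'
#' @param node 0-based node index (used to look up top pathways)
#' @param hTable an [HScoreTable-class]
#' @param expr the filtered [ExpressionMatrix-class]
#' @param chemoProfile named numeric vector over the panel: the node's
#'   codebook profile, or a raw compound profile
#' @param pathways the [PathwayCollection-class] the H-scores were built on
#' @param config a [RunConfig-class]
#' @return data.frame (gene, r, p), ordered by r ascending (most negative
#'   first, ties by gene name); zero rows when no gene qualifies
#' @export
candidatePool <- function(node, hTable, expr, chemoProfile, pathways,
                          config = runConfig()) {
  top <- topPercentilePathways(hTable, node, config@hTopPercentile)
  poolGenes(top, pathways, expr, chemoProfile, config)
}

#' @rdname candidatePool
#' @param pathwayNames character vector of pathway names to pool
#' @param pathways the [PathwayCollection-class] the names refer to
#' @export
poolGenes <- function(pathwayNames, pathways, expr, chemoProfile,
                      config = runConfig()) {
  members <- unique(unlist(geneSets(pathways)[pathwayNames], use.names = FALSE))
  genes <- intersect(geneIds(expr), members)
  if (!length(genes))
    return(data.frame(gene = character(), r = numeric(), p = numeric()))
  E <- exprValues(expr)[genes, , drop = FALSE]
  rn <- .corAgainstProfile(E, chemoProfile)
  r <- rn$r; n <- rn$n
  p <- .corPValue(r, n)
  keep <- !is.na(p) & p < config@corrAlpha
  out <- data.frame(gene = genes[keep], r = r[keep], p = p[keep])
  out[order(out$r, out$gene), , drop = FALSE]
}

# Core iterative two-step trimming loop, shared by trimDiscriminant() and
# the shuffle-null simulation. E: genes x cells expression; geneClass fixed;
# cellSensitive logical. Returns retained indices plus final p-values.
# Separation must be direction-consistent with the class labels: an
# over_sensitive gene must sit higher in sensitive cells, and a sensitive
# cell must express the over_sensitive group above the over_insensitive
# group (the four response classes are directional by definition).
.trimLoop <- function(E, geneClass, cellSensitive, alpha, welch, maxIter) {
  genes <- rownames(E); cells <- colnames(E)
  gkeep <- rep(TRUE, length(genes)); ckeep <- rep(TRUE, length(cells))
  gp <- rep(NA_real_, length(genes)); cp <- rep(NA_real_, length(cells))
  iter <- 0L; status <- "ok"; convergedFlag <- FALSE
  repeat {
    iter <- iter + 1L
    dropped <- FALSE
    # gene step: expression difference between sensitive and insensitive
    sens <- cellSensitive[ckeep]
    if (!any(sens) || all(sens)) {
      status <- sprintf("cell class '%s' emptied",
                        if (any(sens)) "insensitive" else "sensitive")
      break
    }
    tg <- .rowTTest(E[gkeep, ckeep, drop = FALSE], sens, welch)
    gp[gkeep] <- tg$p
    wantUp <- geneClass[gkeep] == "over_sensitive"
    pass <- !is.na(tg$p) & tg$p < alpha &
      (tg$delta > 0) == wantUp
    if (!all(pass)) {
      gkeep[gkeep] <- pass
      dropped <- TRUE
    }
    if (!any(gkeep)) { status <- "gene pool emptied"; break }
    gc_ <- geneClass[gkeep]
    if (!any(gc_ == "over_sensitive") || !any(gc_ == "over_insensitive")) {
      status <- sprintf("gene class '%s' emptied",
                        setdiff(c("over_sensitive", "over_insensitive"),
                                unique(gc_))[1L])
      break
    }
    # cell step: per-cell difference between the over and under gene groups
    ct <- .rowTTest(t(E[gkeep, ckeep, drop = FALSE]),
                    gc_ == "over_sensitive", welch)
    cp[ckeep] <- ct$p
    passc <- !is.na(ct$p) & ct$p < alpha &
      (ct$delta > 0) == cellSensitive[ckeep]
    if (!all(passc)) {
      ckeep[ckeep] <- passc
      dropped <- TRUE
    }
    if (!any(ckeep)) { status <- "cell set emptied"; break }
    cs <- cellSensitive[ckeep]
    if (!any(cs) || all(cs)) {
      status <- sprintf("cell class '%s' emptied",
                        if (any(cs)) "insensitive" else "sensitive")
      break
    }
    if (!dropped) { convergedFlag <- TRUE; break }
    if (iter >= maxIter) { status <- "max iterations reached"; break }
  }
  list(gkeep = gkeep, ckeep = ckeep, gp = gp, cp = cp,
       iterations = iter, converged = convergedFlag, status = status)
}

#' Iterative two-step t-test trimming of a candidate pool
#'
#' Cells start split by the sign of the reference chemoactivity profile
#' (positive = sensitive; exactly zero counts as insensitive). Each pass
#' first drops genes whose expression does not differ between the current
#' sensitive and insensitive cells (two-sample Student's t, `p >=
#' trimAlpha`), then drops cells whose expression does not differ between
#' the current over- and under-expressed gene groups. Gene groups are fixed
#' once by the sign of each gene's initial correlation with the profile.
#' Passes repeat until nothing is dropped, a class empties (failure), or
#' `maxIter` is hit. A degenerate test (a group with fewer than two values)
#' drops the tested item: separability cannot be established for it.
#' Separation must also point the right way — a nominally sensitive cell
#' whose under-expressed group dominates its over-expressed group
#' contradicts its class and is dropped however significant the
#' difference, and likewise for genes.
#'
#' @param pool data.frame from [candidatePool()]/[poolGenes()] (gene, r, p)
#' @param expr the [ExpressionMatrix-class]
#' @param chemoProfile named numeric vector over the panel (NA allowed;
#'   cells with missing chemoactivity are excluded up front)
#' @param config a [RunConfig-class]; uses `trimAlpha`, `welch`, `maxIter`
#' @return a [DiscriminantSet-class]; `@status` is `"ok"` on convergence,
#'   otherwise names the emptied class or the iteration bound
#' @export
trimDiscriminant <- function(pool, expr, chemoProfile, config = runConfig()) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (!nrow(pool))
    return(new("DiscriminantSet", genes = character(),
               geneClass = character(), geneR = numeric(), geneP = numeric(),
               cells = character(), cellClass = character(),
               cellChemo = numeric(), cellP = numeric(),
               nIterations = 0L, converged = FALSE, status = "empty pool"))
  cells <- cellIds(expr)[!is.na(chemoProfile[cellIds(expr)])]
  chemo <- chemoProfile[cells]
  E <- exprValues(expr)[pool$gene, cells, drop = FALSE]
  geneClass <- ifelse(pool$r < 0, "over_insensitive", "over_sensitive")
  sens <- chemo > 0
  res <- .trimLoop(E, geneClass, sens, config@trimAlpha, config@welch,
                   config@maxIter)
  gi <- which(res$gkeep); ci <- which(res$ckeep)
  # final ordering: genes most-negative r first; cells most insensitive first
  gi <- gi[order(pool$r[gi], pool$gene[gi])]
  ci <- ci[order(chemo[ci], cells[ci])]
  new("DiscriminantSet",
      genes = pool$gene[gi],
      geneClass = geneClass[gi],
      geneR = pool$r[gi],
      geneP = res$gp[gi],
      cells = cells[ci],
      cellClass = as.character(ifelse(sens[ci], "sensitive", "insensitive")),
      cellChemo = unname(chemo[ci]),
      cellP = res$cp[ci],
      nIterations = res$iterations,
      converged = res$converged,
      status = res$status)
}

#' Four-quadrant class labels of a discriminant set
#'
#' Partitions every (gene, cell) pair into the four response classes:
#' A = over-expressed/insensitive (negative-r gene, insensitive cell),
#' B = under-expressed/sensitive (negative-r gene, sensitive cell),
#' C = under-expressed/insensitive (positive-r gene, insensitive cell),
#' D = over-expressed/sensitive (positive-r gene, sensitive cell).
#'
#' @param set a [DiscriminantSet-class]
#' @return character matrix genes x cells with entries "A"/"B"/"C"/"D"
#' @export
fourClassLabels <- function(set) {
  stopifnot(is(set, "DiscriminantSet"))
  neg <- set@geneClass == "over_insensitive"
  sens <- set@cellClass == "sensitive"
  lab <- matrix("", length(set@genes), length(set@cells),
                dimnames = list(set@genes, set@cells))
  lab[neg, !sens] <- "A"
  lab[neg, sens] <- "B"
  lab[!neg, !sens] <- "C"
  lab[!neg, sens] <- "D"
  lab
}

#' Shuffle-null false-positive probability of the trimming procedure
#'
#' Estimates how likely a pure-noise gene is to survive both trimming
#' t-tests. Each permutation round independently shuffles every retained
#' gene's expression values across the retained cells and re-runs the full
#' two-step trim (original gene and cell classes); the returned estimate is
#' the fraction of shuffled genes that survive. On real converged sets this
#' lies orders of magnitude below the nominal threshold, because survival
#' requires jointly passing the gene-dimension test and sitting in a
#' cell-set that still passes the cell-dimension tests.
#'
#' @param set a converged [DiscriminantSet-class]
#' @param expr the [ExpressionMatrix-class] the set was trimmed from
#' @param config a [RunConfig-class]
#' @param nPerm total number of gene shuffles, at least 100
#' @param seed RNG seed (defaults to the config seed)
#' @return list: `fpr` (estimated false-positive probability),
#'   `n_shuffled`, `n_passed`
#' @export
shuffleNullFPR <- function(set, expr, config = runConfig(), nPerm = 10000L,
                           seed = config@rngSeed) {
  stopifnot(is(set, "DiscriminantSet"))
  if (nPerm < 100L) stop("nPerm must be >= 100 for a meaningful estimate")
  ng <- length(set@genes)
  if (ng < 1L) stop("discriminant set has no genes")
  E0 <- exprValues(expr)[set@genes, set@cells, drop = FALSE]
  sens <- set@cellClass == "sensitive"
  rounds <- ceiling(nPerm / ng)
  passed <- 0L; total <- 0L
  .withSeed(seed, {
    for (b in seq_len(rounds)) {
      Es <- t(apply(E0, 1L, sample))
      dimnames(Es) <- dimnames(E0)
      res <- .trimLoop(Es, set@geneClass, sens, config@trimAlpha,
                       config@welch, config@maxIter)
      survivors <- if (res$status %in% c("ok") || res$converged)
        sum(res$gkeep) else 0L
      # a run that broke down (class emptied) retains no validated gene
      passed <- passed + survivors
      total <- total + ng
    }
  })
  list(fpr = passed / total, n_shuffled = total, n_passed = passed)
}
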