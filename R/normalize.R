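#' Filter raw chemoactivity profiles by coverage and variation
#'
#' Keeps only profiles where strictly more than `minCells` cell lines
#' reported values and whose coefficient of variation (sd / |mean| over
#' non-missing entries) is at least `minCV`. Profiles with fewer than two
#' non-missing values are dropped (their CV is undefined), counted under the
#' coverage rule. Minimal-variation profiles typically reflect compound
#' insensitivity or pan-cytotoxicity and carry no differential signal.
#'
#' @param x a raw (un-normalized) [ChemoProfileSet-class]
#' @param minCells strict lower bound on reported cells (default 40)
#' @param minCV minimal coefficient of variation (default 0.05)
#' @return list with elements `profiles` (the filtered set, input order
#'   preserved) and `report` (a one-row data.frame: n_input, n_kept,
#'   n_dropped_min_cells, n_dropped_cv)
#' @export
filterChemoProfiles <- function(x, minCells = 40, minCV = 0.05) {
  stopifnot(is(x, "ChemoProfileSet"))
  if (isNormalized(x))
    stop("filterChemoProfiles expects raw (un-normalized) profiles")
  v <- chemoValues(x)
  nobs <- rowSums(!is.na(v))
  okCells <- nobs > minCells
  cv <- .rowCV(v)
  okCV <- !is.na(cv) & cv >= minCV
  keep <- okCells & okCV
  report <- data.frame(
    n_input = nrow(v),
    n_kept = sum(keep),
    n_dropped_min_cells = sum(!okCells),
    n_dropped_cv = sum(okCells & !okCV))
  list(profiles = ChemoProfileSet(v[keep, , drop = FALSE]), report = report)
}

#' Two-stage normalization of chemoactivity profiles
#'
#' Stage 1 normalizes across tumor cell type: each cell line's column is
#' standardized over all compounds (non-missing), removing systematic biases
#' from individually hyper- or hypo-sensitive lines. Stage 2 z-scores each
#' compound's record over its non-missing cells. The result is the
#' compound's GI50 z-score profile: mean 0, sd 1 per profile, positive
#' values marking sensitive cells. A cell line whose column has zero
#' variance is centered only at stage 1 (with a warning).
#'
#' Applying the function twice changes nothing beyond 1e-8: stage 1 on
#' per-column-recentred z-scores is (numerically) the identity and stage 2
#' is idempotent.
#'
#' @param x a filtered, raw [ChemoProfileSet-class]
#' @param stage1 `"zscore"` (default) to fully standardize each cell column,
#'   `"center"` to subtract the column mean only
#' @return a normalized [ChemoProfileSet-class]
#' @export
normalizeChemo <- function(x, stage1 = c("zscore", "center")) {
  stopifnot(is(x, "ChemoProfileSet"))
  stage1 <- match.arg(stage1)
  v <- chemoValues(x)
  # stage 1: across tumor cell type. Skipped when the set is already
  # normalized (repeat calls are then the identity up to float noise) and
  # for single-compound sets, where a per-cell statistic is undefined.
  if (!isNormalized(x) && nrow(v) > 1L) {
    cm <- colMeans(v, na.rm = TRUE)
    v <- sweep(v, 2L, cm, "-")
    if (stage1 == "zscore") {
      cs <- apply(v, 2L, stats::sd, na.rm = TRUE)
      flat <- !is.na(cs) & cs == 0
      if (any(flat)) {
        warning(sum(flat),
                " cell line(s) with zero variance across compounds;",
                " stage-1 division skipped (centered only)")
        cs[flat] <- 1
      }
      cs[is.na(cs)] <- 1
      v <- sweep(v, 2L, cs, "/")
    }
  }
  # stage 2: within each record
  rm_ <- rowMeans(v, na.rm = TRUE)
  v <- sweep(v, 1L, rm_, "-")
  rs <- apply(v, 1L, stats::sd, na.rm = TRUE)
  if (any(is.na(rs) | rs == 0))
    stop("profile(s) with zero variance after stage 1 cannot be z-scored; ",
         "filter first")
  v <- sweep(v, 1L, rs, "/")
  ChemoProfileSet(v, normalized = TRUE)
}

#' Filter expression genes by variation and pathway co-membership
#'
#' Keeps genes whose coefficient of variation exceeds `minCV` and that share
#' at least one pathway with at least one *other* measured gene. A pathway
#' whose only measured member is the gene itself does not rescue it.
#'
#' @param expr an [ExpressionMatrix-class]
#' @param pathways a [PathwayCollection-class] (raw, pre-filtering)
#' @param minCV strict lower bound on the coefficient of variation
#' @param caseInsensitive match symbols case-insensitively (off by default;
#'   silent case-folding makes overlaps irreproducible)
#' @return the filtered [ExpressionMatrix-class], input gene order preserved
#' @export
filterExpressionGenes <- function(expr, pathways, minCV = 0.05,
                                  caseInsensitive = FALSE) {
  stopifnot(is(expr, "ExpressionMatrix"), is(pathways, "PathwayCollection"))
  v <- exprValues(expr)
  genes <- rownames(v)
  cv <- .rowCV(v)
  okCV <- !is.na(cv) & cv > minCV
  key <- if (caseInsensitive) toupper(genes) else genes
  shared <- rep(FALSE, length(genes))
  for (s in geneSets(pathways)) {
    ms <- if (caseInsensitive) toupper(s) else s
    hit <- key %in% ms
    if (sum(hit) >= 2L) shared <- shared | hit
  }
  keep <- okCV & shared
  if (!any(keep)) warning("no genes survive expression filtering")
  ExpressionMatrix(v[keep, , drop = FALSE])
}

#' Retain pathways with enough measured member genes
#'
#' @param pathways a [PathwayCollection-class]
#' @param expr the already-filtered [ExpressionMatrix-class]
#' @param minPresent minimal count of members present among measured genes
#'   (default 2: an H-score needs at least two member correlations)
#' @param caseInsensitive match symbols case-insensitively
#' @return the filtered [PathwayCollection-class]
#' @export
filterPathways <- function(pathways, expr, minPresent = 2L,
                           caseInsensitive = FALSE) {
  stopifnot(is(pathways, "PathwayCollection"), is(expr, "ExpressionMatrix"))
  genes <- geneIds(expr)
  if (caseInsensitive) genes <- toupper(genes)
  present <- vapply(geneSets(pathways), function(s) {
    if (caseInsensitive) s <- toupper(s)
    sum(s %in% genes)
  }, integer(1))
  pathways[present >= minPresent]
}
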