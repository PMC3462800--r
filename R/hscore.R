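#' Pearson correlation over jointly observed entries
#'
#' @param x,y equal-length numeric vectors, NA = missing
#' @return list with `r` (NA when fewer than 3 joint observations or either
#'   side has zero variance over them) and `n` (joint observation count)
#' @export
pearsonMasked <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  .pearsonPair(x, y)
}

#' Correlate every gene with every SOM codebook (or raw) profile
#'
#' @param expr a filtered [ExpressionMatrix-class]
#' @param model a [SOMModel-class] (columns are 0-based node indices) or a
#'   numeric profile matrix / vector over the same panel (columns are its
#'   row names, or `"profile"` for a bare vector)
#' @return list: `r` (genes x profiles Pearson matrix, NA where undefined)
#'   and `n` (joint non-missing counts); entries with n < 3 are masked
#' @export
geneNodeCorrelations <- function(expr, model) {
  stopifnot(is(expr, "ExpressionMatrix"))
  E <- exprValues(expr)
  if (is(model, "SOMModel")) {
    P <- codebook(model)
    rownames(P) <- as.character(seq_len(nrow(P)) - 1L)
  } else if (is.matrix(model)) {
    P <- model
    if (is.null(rownames(P)))
      rownames(P) <- sprintf("profile%d", seq_len(nrow(P)))
  } else {
    P <- matrix(model, nrow = 1L, dimnames = list("profile", names(model)))
  }
  if (ncol(E) != ncol(P) ||
      (!is.null(colnames(P)) && !identical(colnames(E), colnames(P))))
    stop("expression and profile panels do not match")
  r <- suppressWarnings(stats::cor(t(E), t(P),
                                   use = "pairwise.complete.obs"))
  n <- (!is.na(E)) %*% t(!is.na(P))
  r[n < 3L] <- NA_real_
  dimnames(r) <- dimnames(n) <- list(rownames(E), rownames(P))
  list(r = r, n = n)
}

#' Kruskal-Wallis rank statistic for two groups
#'
#' Midrank ties, tie-corrected:
#' `H = (12 / (N (N + 1))) * sum n_g (Rbar_g - (N + 1) / 2)^2 / C` with
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie group sizes `t`. The p-value
#' uses the chi-square approximation with 1 degree of freedom. When all
#' values are tied, `H = 0` and `p = 1`.
#'
#' @param a,b numeric value vectors of the two groups (jointly ranked)
#' @return list with `H` and `p`
#' @export
kruskalWallisH <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  x <- c(a, b)
  N <- length(x)
  r <- rank(x)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) return(list(H = 0, p = 1))
  m <- (N + 1) / 2
  Ra <- mean(r[seq_along(a)])
  Rb <- mean(r[length(a) + seq_along(b)])
  H <- (12 / (N * (N + 1))) *
    (length(a) * (Ra - m)^2 + length(b) * (Rb - m)^2) / C
  list(H = H, p = max(stats::pchisq(H, df = 1, lower.tail = FALSE),
                      .Machine$double.xmin))
}

#' Signed pathway H-score for one profile's correlation column
#'
#' Jointly ranks the correlation strengths (|r|) of pathway-member and
#' non-member genes and measures non-random ranking by the two-group
#' Kruskal-Wallis statistic: member genes of a chemo-important pathway sit
#' skewed towards the extreme correlation values, in either direction. The
#' score is signed positive when the mean member correlation strength
#' exceeds the mean non-member strength (coordinated association of the
#' pathway with the chemoactivity profile), negative otherwise. Ranking on
#' magnitudes rather than raw values keeps a pathway whose genes associate
#' coherently but in both directions — over-expression marking sensitivity
#' for some members, resistance for others, as the four response classes
#' require — at the top of the score distribution. Undefined correlations
#' are excluded from both groups before ranking.
#'
#' @param corrColumn named numeric vector of per-gene correlations (NA
#'   allowed)
#' @param members logical vector (or character vector of member gene names)
#'   marking pathway membership
#' @return one-row data.frame: H (signed), p, n_in, n_out, mean_r_in,
#'   mean_r_out (group means of the ranked correlation strengths), valid
#' @export
pathwayH <- function(corrColumn, members) {
  if (is.character(members)) members <- names(corrColumn) %in% members
  corrColumn <- abs(corrColumn)
  def <- !is.na(corrColumn)
  rin <- corrColumn[def & members]
  rout <- corrColumn[def & !members]
  if (length(rin) < 2L || length(rout) < 1L)
    return(data.frame(H = NA_real_, p = NA_real_, n_in = length(rin),
                      n_out = length(rout), mean_r_in = NA_real_,
                      mean_r_out = NA_real_, valid = FALSE))
  kw <- kruskalWallisH(rin, rout)
  s <- sign(mean(rin) - mean(rout))
  data.frame(H = kw$H * if (s == 0) 1 else s, p = kw$p,
             n_in = length(rin), n_out = length(rout),
             mean_r_in = mean(rin), mean_r_out = mean(rout), valid = TRUE)
}

#' Full pathway-by-node H-score table
#'
#' Computes one signed H-score record per retained pathway per profile
#' column. Accepts either a gene-node correlation object from
#' [geneNodeCorrelations()] or the pieces to build one (expression plus a
#' SOM model or raw profile), so the same scoring runs against a single raw
#' compound profile when needed.
#'
#' @param corr result of [geneNodeCorrelations()] (list with `r`)
#' @param pathways a filtered [PathwayCollection-class]
#' @return an [HScoreTable-class]
#' @export
hScoreTable <- function(corr, pathways) {
  stopifnot(is(pathways, "PathwayCollection"))
  R <- corr$r
  genes <- rownames(R)
  sets <- geneSets(pathways)
  # pathway x gene membership indicator, computed once
  P <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  P <- t(P)  # npw x ngenes
  npw <- nrow(P)
  out <- vector("list", ncol(R))
  for (j in seq_len(ncol(R))) {
    rcol <- abs(R[, j])   # rank correlation strengths; see pathwayH()
    def <- !is.na(rcol)
    rv <- rcol[def]
    N <- length(rv)
    rk <- rank(rv)
    tie <- table(rv)
    C <- 1 - sum(tie^3 - tie) / max(N^3 - N, 1)
    Pd <- P[, def, drop = FALSE]
    n_in <- as.numeric(Pd %*% rep(1, N))
    n_out <- N - n_in
    sumRk <- as.numeric(Pd %*% rk)
    sumR <- as.numeric(Pd %*% rv)
    m <- (N + 1) / 2
    Rin <- sumRk / n_in
    Rout <- (sum(rk) - sumRk) / n_out
    H <- (12 / (N * (N + 1))) *
      (n_in * (Rin - m)^2 + n_out * (Rout - m)^2)
    H <- if (C > 0) H / C else rep(0, npw)
    mean_in <- sumR / n_in
    mean_out <- (sum(rv) - sumR) / n_out
    sgn <- sign(mean_in - mean_out)
    sgn[sgn == 0] <- 1
    valid <- n_in >= 2 & n_out >= 1
    p <- pmax(stats::pchisq(H, df = 1, lower.tail = FALSE),
              .Machine$double.xmin)
    out[[j]] <- data.frame(
      pathway = rownames(P), node = colnames(R)[j],
      H = ifelse(valid, H * sgn, NA_real_),
      p = ifelse(valid, p, NA_real_),
      n_in = as.integer(n_in), n_out = as.integer(n_out),
      mean_r_in = ifelse(valid, mean_in, NA_real_),
      mean_r_out = ifelse(valid, mean_out, NA_real_),
      valid = valid, row.names = NULL)
  }
  new("HScoreTable", records = do.call(rbind, out))
}

#' Pathways in the top percentile of signed H-scores at a node
#'
#' Selects the `ceiling(percentile / 100 * n)` best pathways by signed H
#' (descending), extending the cut to include any pathway tied with the
#' boundary score. Ties in ordering break alphabetically by pathway name.
#'
#' @param table an [HScoreTable-class]
#' @param node node identifier (0-based index, matched as character)
#' @param percentile top percentile to keep, default 10
#' @return character vector of pathway names, best first
#' @export
topPercentilePathways <- function(table, node, percentile = 10) {
  stopifnot(is(table, "HScoreTable"))
  r <- hRecords(table)
  r <- r[r$node == as.character(node) & r$valid, , drop = FALSE]
  if (!nrow(r)) return(character())
  r <- r[order(-r$H, r$pathway), , drop = FALSE]
  k <- ceiling(percentile / 100 * nrow(r))
  cut <- r$H[k]
  r$pathway[r$H >= cut]
}
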