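#' Hypergeometric upper-tail probability of a gene-set overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` members of a size-`K` set when sampling `n` genes without
#' replacement from a universe of `N`. Evaluated through the log-space
#' upper-tail routine of the stats distribution functions; `k = 0` returns
#' exactly 1.
#'
#' @param k observed overlap count
#' @param K set size within the universe
#' @param n query size
#' @param N universe size
#' @return upper-tail probability in (0, 1]
#' @export
hypergeometricTail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || k > min(K, n) || max(K, n) > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric overlap enrichment of a query gene list
#'
#' Tests every set of the collection for over-representation among the
#' query genes, conditional on a declared universe (the genes that survived
#' expression filtering, so that overlap probabilities condition on what
#' was measurable). Query genes outside the universe are dropped with a
#' warning. Only the upper tail is tested (enrichment, not depletion).
#' Benjamini-Hochberg adjusted p-values are computed across all sets with
#' at least one universe member; the report keeps sets sharing at least
#' `minOverlap` genes, sorted by raw p ascending, ties by set name.
#'
#' @param queryGenes character vector (e.g. genes of a
#'   [DiscriminantSet-class])
#' @param collection a [PathwayCollection-class]
#' @param universe character vector of all eligible genes
#' @param config a [RunConfig-class]; `minOverlap` is used
#' @param topK optional truncation of the report
#' @return data.frame: name, description, source, k, K, n, N, p,
#'   p_adjusted, genes (comma-separated overlap symbols)
#' @export
enrichmentReport <- function(queryGenes, collection, universe,
                             config = runConfig(), topK = NULL) {
  stopifnot(is(collection, "PathwayCollection"))
  universe <- unique(universe)
  N <- length(universe)
  if (!N) stop("empty universe")
  drop <- setdiff(queryGenes, universe)
  if (length(drop))
    warning(length(drop), " query gene(s) outside the universe dropped: ",
            paste(utils::head(drop, 5L), collapse = ", "))
  query <- intersect(unique(queryGenes), universe)
  n <- length(query)
  sets <- geneSets(collection)
  rows <- lapply(pathwayNames(collection), function(nm) {
    inU <- intersect(sets[[nm]], universe)
    K <- length(inU)
    if (!K) return(NULL)
    ov <- intersect(inU, query)
    k <- length(ov)
    data.frame(name = nm, description = collection@description[[nm]],
               source = collection@source[[nm]], k = k, K = K, n = n, N = N,
               p = hypergeometricTail(k, K, n, N),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  if (is.null(rep_) || !nrow(rep_))
    return(data.frame(name = character(), description = character(),
                      source = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adjusted = numeric(), genes = character()))
  rep_$p_adjusted <- stats::p.adjust(rep_$p, method = "BH")
  rep_ <- rep_[rep_$k >= config@minOverlap, , drop = FALSE]
  rep_ <- rep_[order(rep_$p, rep_$name), , drop = FALSE]
  if (!is.null(topK)) rep_ <- utils::head(rep_, topK)
  rownames(rep_) <- NULL
  rep_[, c("name", "description", "source", "k", "K", "n", "N", "p",
           "p_adjusted", "genes")]
}
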