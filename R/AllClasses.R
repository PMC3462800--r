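#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.checkPanel <- function(ids) {
  if (length(ids) < 2L)
    return("panel must contain at least 2 cell lines")
  if (anyDuplicated(ids))
    return(sprintf("duplicate cell ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  NULL
}

# ---- ExpressionMatrix -------------------------------------------------------

#' Constitutive gene-expression matrix on a cell panel
#'
#' A gene-by-cell matrix of baseline (untreated) expression values, stored as
#' a thin \linkS4class{SummarizedExperiment} with a single `"exprs"` assay.
#' Row names are unique gene symbols (HUGO-style); column names are the cell
#' panel. Missing measurements are `NA` and stay masked through every stage.
#'
#' @slot .Data inherited SummarizedExperiment backbone
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

#' @describeIn ExpressionMatrix-class construct from a numeric matrix with
#'   gene-symbol rownames and cell-id colnames; `tissue` is an optional
#'   per-cell label stored in `colData`.
#' @param values numeric matrix, genes x cells, `NA` for missing
#' @param tissue optional character vector of per-cell tissue labels
#' @return an `ExpressionMatrix`
#' @export
ExpressionMatrix <- function(values, tissue = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(tissue)) cd$tissue <- tissue
  new("ExpressionMatrix",
      SummarizedExperiment(assays = list(exprs = values), colData = cd))
}

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  v <- assay(object, "exprs")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, sprintf(
      "gene symbols must be unique; duplicated: %s",
      paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
  p <- .checkPanel(colnames(v))
  if (!is.null(p)) msgs <- c(msgs, p)
  if (length(msgs)) msgs else TRUE
})

#' Expression values of an ExpressionMatrix
#' @param x an ExpressionMatrix
#' @return numeric matrix (genes x cells) with NA for missing
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @rdname cellIds
#' @export
setMethod("cellIds", "SummarizedExperiment", function(x) colnames(x))

#' @rdname geneIds
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  v <- assay(object, "exprs")
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
})

# ---- ChemoProfileSet --------------------------------------------------------

#' Compound chemoactivity (GI50-derived) profiles on a cell panel
#'
#' A compound-by-cell matrix of GI50-derived chemoactivity values stored as a
#' \linkS4class{SummarizedExperiment} with one `"chemo"` assay. After
#' [normalizeChemo()] each profile is a z-score over its non-missing cells and
#' the sign convention is: positive = sensitive cell, negative = insensitive.
#'
#' @slot normalized logical; `TRUE` once two-stage normalization has run
#' @export
setClass("ChemoProfileSet",
         contains = "SummarizedExperiment",
         representation(normalized = "logical"),
         prototype(normalized = FALSE))

#' @describeIn ChemoProfileSet-class construct from a numeric matrix with
#'   compound-id rownames and cell-id colnames.
#' @param values numeric matrix, compounds x cells, `NA` for missing
#' @param normalized logical flag; set by [normalizeChemo()]
#' @return a `ChemoProfileSet`
#' @export
ChemoProfileSet <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ChemoProfileSet",
      SummarizedExperiment(assays = list(chemo = values)),
      normalized = normalized)
}

setValidity("ChemoProfileSet", function(object) {
  msgs <- character()
  v <- assay(object, "chemo")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "compound ids must be unique")
  p <- .checkPanel(colnames(v))
  if (!is.null(p)) msgs <- c(msgs, p)
  if (isTRUE(object@normalized)) {
    m <- rowMeans(v, na.rm = TRUE)
    s <- apply(v, 1L, stats::sd, na.rm = TRUE)
    bad <- abs(m) > 1e-8 | abs(s - 1) > 1e-8
    if (any(bad, na.rm = TRUE))
      msgs <- c(msgs, sprintf(
        "%d profile(s) flagged normalized but not mean 0 / sd 1", sum(bad)))
  }
  if (length(msgs)) msgs else TRUE
})

#' Chemoactivity values of a ChemoProfileSet
#' @param x a ChemoProfileSet
#' @return numeric matrix (compounds x cells) with NA for missing
#' @export
chemoValues <- function(x) assay(x, "chemo")

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "ChemoProfileSet", function(x) rownames(x))

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "ChemoProfileSet", function(x) x@normalized)

setMethod("show", "ChemoProfileSet", function(object) {
  v <- assay(object, "chemo")
  cat(sprintf("ChemoProfileSet: %d compounds x %d cells (%.1f%% missing)%s\n",
              nrow(v), ncol(v), 100 * mean(is.na(v)),
              if (object@normalized) ", normalized" else ", raw"))
})

# ---- PathwayCollection ------------------------------------------------------

#' A collection of named gene sets (pathways)
#'
#' Flat gene sets in the GMT sense: a unique name, a free-text description, a
#' source tag (KEGG / GO / Biocarta / ...), and a non-empty set of member gene
#' symbols. Symbol matching against expression rows is exact and
#' case-sensitive after whitespace trimming unless explicitly relaxed.
#'
#' @slot sets named list of character vectors (member symbols, de-duplicated)
#' @slot description named character, one per set
#' @slot source named character, one per set
#' @export
setClass("PathwayCollection",
         representation(sets = "list", description = "character",
                        source = "character"))

#' @describeIn PathwayCollection-class constructor.
#' @param sets named list of character vectors of gene symbols
#' @param description per-set description (recycled if length 1)
#' @param source per-set source tag (recycled if length 1)
#' @return a `PathwayCollection`
#' @export
PathwayCollection <- function(sets, description = "", source = "custom") {
  nm <- names(sets)
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  names(sets) <- nm
  if (length(description) == 1L) description <- rep(description, length(sets))
  if (length(source) == 1L) source <- rep(source, length(sets))
  names(description) <- names(source) <- nm
  new("PathwayCollection", sets = sets, description = description,
      source = source)
}

setValidity("PathwayCollection", function(object) {
  msgs <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msgs <- c(msgs, "pathway names must be unique and non-NULL")
  if (any(lengths(object@sets) == 0L))
    msgs <- c(msgs, "gene sets must be non-empty")
  if (length(object@description) != length(object@sets) ||
      length(object@source) != length(object@sets))
    msgs <- c(msgs, "description/source must align with sets")
  if (length(msgs)) msgs else TRUE
})

#' @rdname pathwayNames
#' @export
setMethod("pathwayNames", "PathwayCollection", function(x) names(x@sets))

#' @rdname geneSets
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' Number of pathways in a collection
#' @param x a PathwayCollection
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' Subset a pathway collection by name or index
#' @param x a PathwayCollection
#' @param i names or indices
#' @param j,drop,... ignored
#' @export
setMethod("[", "PathwayCollection", function(x, i, j, ..., drop = FALSE) {
  new("PathwayCollection", sets = x@sets[i],
      description = x@description[i], source = x@source[i])
})

setMethod("show", "PathwayCollection", function(object) {
  cat(sprintf("PathwayCollection: %d sets, sizes %d-%d, sources: %s\n",
              length(object@sets),
              if (length(object@sets)) min(lengths(object@sets)) else 0L,
              if (length(object@sets)) max(lengths(object@sets)) else 0L,
              paste(unique(object@source), collapse = "/")))
})

# ---- RunConfig --------------------------------------------------------------

#' Pipeline configuration
#'
#' Holds every tunable threshold of the workflow. Defaults follow the
#' published NCI60 analysis settings: profiles need reported values in more
#' than `minCellsReported` cells and a coefficient of variation of at least
#' `minCV`; the map is `somRows x somCols`; candidate pathways come from the
#' `hTopPercentile` top percentile of signed H-scores; gene-chemoactivity
#' correlations and all trimming t-tests use nominal `corrAlpha` / `trimAlpha`
#' thresholds; LDA accuracy uses `ldaFolds`-fold cross-validation; enrichment
#' reports sets sharing at least `minOverlap` genes.
#'
#' @slot minCellsReported strict lower bound on non-missing cells per profile
#' @slot minCV minimal coefficient of variation (profiles and genes)
#' @slot somRows,somCols map grid dimensions
#' @slot somEpochs training epochs of the batch SOM
#' @slot hTopPercentile top percentile (0-100] of signed H-scores kept
#' @slot corrAlpha two-sided p threshold on gene-profile correlations
#' @slot trimAlpha p threshold of the iterative trimming t-tests
#' @slot ldaFolds number of cross-validation folds
#' @slot minOverlap minimal overlap count reported by enrichment
#' @slot maxIter safety bound on trimming iterations
#' @slot stage1 `"zscore"` (default) or `"center"`: across-cell normalization
#' @slot welch use Welch instead of pooled-variance t-tests
#' @slot conventionalMode `"alpha"` or `"percentile"` baseline gene cut
#' @slot conventionalValue threshold for the baseline cut
#' @slot rngSeed integer seed driving all randomized stages
#' @export
setClass("RunConfig", representation(
  minCellsReported = "numeric", minCV = "numeric",
  somRows = "integer", somCols = "integer", somEpochs = "integer",
  hTopPercentile = "numeric", corrAlpha = "numeric", trimAlpha = "numeric",
  ldaFolds = "integer", minOverlap = "integer", maxIter = "integer",
  stage1 = "character", welch = "logical",
  conventionalMode = "character", conventionalValue = "numeric",
  rngSeed = "integer"))

#' @describeIn RunConfig-class constructor with published defaults.
#' @param minCellsReported,minCV,somRows,somCols,somEpochs,hTopPercentile
#'   see slots
#' @param corrAlpha,trimAlpha,ldaFolds,minOverlap,maxIter see slots
#' @param stage1,welch,conventionalMode,conventionalValue,rngSeed see slots
#' @return a validated `RunConfig`
#' @export
runConfig <- function(minCellsReported = 40, minCV = 0.05,
                      somRows = 54L, somCols = 37L, somEpochs = 50L,
                      hTopPercentile = 10, corrAlpha = 0.05,
                      trimAlpha = 0.05, ldaFolds = 5L, minOverlap = 2L,
                      maxIter = 100L, stage1 = c("zscore", "center"),
                      welch = FALSE,
                      conventionalMode = c("alpha", "percentile"),
                      conventionalValue = 0.05, rngSeed = 1L) {
  new("RunConfig",
      minCellsReported = minCellsReported, minCV = minCV,
      somRows = as.integer(somRows), somCols = as.integer(somCols),
      somEpochs = as.integer(somEpochs),
      hTopPercentile = hTopPercentile, corrAlpha = corrAlpha,
      trimAlpha = trimAlpha, ldaFolds = as.integer(ldaFolds),
      minOverlap = as.integer(minOverlap), maxIter = as.integer(maxIter),
      stage1 = match.arg(stage1), welch = welch,
      conventionalMode = match.arg(conventionalMode),
      conventionalValue = conventionalValue, rngSeed = as.integer(rngSeed))
}

setValidity("RunConfig", function(object) {
  msgs <- character()
  for (sl in c("corrAlpha", "trimAlpha"))
    if (slot(object, sl) <= 0 || slot(object, sl) >= 1)
      msgs <- c(msgs, sprintf("%s must be in (0,1)", sl))
  if (object@somRows < 1L || object@somCols < 1L)
    msgs <- c(msgs, "grid dimensions must be >= 1")
  if (object@hTopPercentile <= 0 || object@hTopPercentile > 100)
    msgs <- c(msgs, "hTopPercentile must be in (0,100]")
  if (object@ldaFolds < 2L) msgs <- c(msgs, "ldaFolds must be >= 2")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(paste0(
    "RunConfig: SOM %dx%d (%d epochs) | profiles: >%g cells, CV>=%g\n",
    "  H top %g%% | corr alpha %g | trim alpha %g (%s t) | LDA %d-fold\n",
    "  enrichment min overlap %d | seed %d\n"),
    object@somRows, object@somCols, object@somEpochs,
    object@minCellsReported, object@minCV, object@hTopPercentile,
    object@corrAlpha, object@trimAlpha,
    if (object@welch) "Welch" else "pooled", object@ldaFolds,
    object@minOverlap, object@rngSeed))
})

# ---- SOMModel ---------------------------------------------------------------

#' A trained self-organizing map of chemoactivity profiles
#'
#' Rectangular grid of codebook vectors over the cell panel. Nodes are
#' indexed row-major and 0-based: node `k` sits at grid row `k %/% cols`,
#' column `k %% cols`. Each codebook row is the "SOM GI50 profile" of its
#' cluster and contains no missing entries.
#'
#' @slot rows,cols grid dimensions
#' @slot codebook numeric matrix, (rows*cols) x |panel|, finite
#' @slot trainParams list: epochs, lr0, lr1, radius0, radius1
#' @slot seed integer seed the training run used
#' @slot qeLog numeric; mean quantization error recorded after each epoch
#' @export
setClass("SOMModel", representation(
  rows = "integer", cols = "integer", codebook = "matrix",
  trainParams = "list", seed = "integer", qeLog = "numeric"))

setValidity("SOMModel", function(object) {
  msgs <- character()
  if (nrow(object@codebook) != object@rows * object@cols)
    msgs <- c(msgs, "codebook must have rows*cols vectors")
  if (any(!is.finite(object@codebook)))
    msgs <- c(msgs, "codebook vectors must be finite")
  if (is.null(colnames(object@codebook)))
    msgs <- c(msgs, "codebook columns must carry cell ids")
  if (length(msgs)) msgs else TRUE
})

#' @rdname nNodes
#' @export
setMethod("nNodes", "SOMModel", function(x) x@rows * x@cols)

#' @rdname codebook
#' @export
setMethod("codebook", "SOMModel", function(x) x@codebook)

#' @rdname cellIds
#' @export
setMethod("cellIds", "SOMModel", function(x) colnames(x@codebook))

setMethod("show", "SOMModel", function(object) {
  cat(sprintf(
    "SOMModel: %dx%d grid (%d nodes) over %d cells, %d epochs, seed %d\n",
    object@rows, object@cols, nNodes(object), ncol(object@codebook),
    object@trainParams$epochs, object@seed))
  if (length(object@qeLog))
    cat(sprintf("  quantization error: %.4f -> %.4f\n",
                object@qeLog[1L], object@qeLog[length(object@qeLog)]))
})

# ---- HScoreTable ------------------------------------------------------------

#' Pathway-by-node signed Kruskal-Wallis H-score table
#'
#' One record per retained pathway per map node. `H` is the Kruskal-Wallis
#' rank statistic over member vs non-member gene correlations, signed
#' positive when member correlations exceed non-member correlations on
#' average; `p` comes from the chi-square(1) approximation of unsigned H.
#'
#' @slot records data.frame: pathway, node, H, p, n_in, n_out, mean_r_in,
#'   mean_r_out, valid
#' @export
setClass("HScoreTable", representation(records = "data.frame"))

setValidity("HScoreTable", function(object) {
  need <- c("pathway", "node", "H", "p", "n_in", "n_out",
            "mean_r_in", "mean_r_out", "valid")
  if (!all(need %in% names(object@records)))
    return(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  r <- object@records[object@records$valid, , drop = FALSE]
  if (nrow(r)) {
    if (any(r$p <= 0 | r$p > 1)) return("p must lie in (0,1]")
    if (any(r$n_in < 2)) return("valid records need >= 2 member genes")
    sgn <- sign(r$mean_r_in - r$mean_r_out)
    if (any(sign(r$H) != sgn & r$H != 0))
      return("sign(H) must equal sign(mean_r_in - mean_r_out)")
  }
  TRUE
})

#' @rdname hRecords
#' @export
setMethod("hRecords", "HScoreTable", function(x) x@records)

setMethod("show", "HScoreTable", function(object) {
  r <- object@records
  cat(sprintf("HScoreTable: %d records (%d pathways x %d nodes), %d valid\n",
              nrow(r), length(unique(r$pathway)), length(unique(r$node)),
              sum(r$valid)))
})

# ---- DiscriminantSet --------------------------------------------------------

#' Trimmed discriminating genes and cells for one chemoactivity profile
#'
#' Result of the iterative two-step t-test trimming. Genes are ordered by
#' their initial correlation with the chemoactivity profile (most negative
#' first); cells by chemoactivity (most insensitive first). Gene class is
#' fixed by the initial correlation sign: `"over_insensitive"` (r < 0) or
#' `"over_sensitive"` (r > 0). Cell class is `"sensitive"` (chemoactivity
#' > 0) or `"insensitive"` (<= 0). On a converged set every gene separates
#' the two cell classes and every cell separates the two gene classes at the
#' trimming threshold.
#'
#' @slot genes,geneClass,geneR,geneP per-gene vectors, aligned
#' @slot cells,cellClass,cellChemo,cellP per-cell vectors, aligned
#' @slot nIterations trimming passes executed
#' @slot converged TRUE if both separability invariants hold
#' @slot status "ok" or a failure description (e.g. an emptied class)
#' @export
setClass("DiscriminantSet", representation(
  genes = "character", geneClass = "character", geneR = "numeric",
  geneP = "numeric", cells = "character", cellClass = "character",
  cellChemo = "numeric", cellP = "numeric", nIterations = "integer",
  converged = "logical", status = "character"))

setValidity("DiscriminantSet", function(object) {
  msgs <- character()
  ng <- length(object@genes)
  if (length(object@geneClass) != ng || length(object@geneR) != ng ||
      length(object@geneP) != ng)
    msgs <- c(msgs, "per-gene slots must align")
  nc <- length(object@cells)
  if (length(object@cellClass) != nc || length(object@cellP) != nc ||
      length(object@cellChemo) != nc)
    msgs <- c(msgs, "per-cell slots must align")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DiscriminantSet", function(object) {
  cat(sprintf(
    "DiscriminantSet [%s]: %d genes (%d over_insensitive / %d over_sensitive), %d cells (%d sensitive / %d insensitive), %d iterations\n",
    object@status, length(object@genes),
    sum(object@geneClass == "over_insensitive"),
    sum(object@geneClass == "over_sensitive"),
    length(object@cells), sum(object@cellClass == "sensitive"),
    sum(object@cellClass == "insensitive"), object@nIterations))
})
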