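#' @import methods
NULL

#' Cell-line identifiers of a panel-shaped object
#'
#' Every matrix-backed object in chemopath (expression, chemoactivity, SOM
#' codebook) is aligned to an ordered panel of tumor cell lines. `cellIds()`
#' returns that ordering; it is preserved through every pipeline stage and is
#' never re-sorted by name.
#'
#' @param x an object with a cell panel dimension
#' @return character vector of unique cell-line identifiers
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Gene identifiers of an expression matrix
#' @param x an [ExpressionMatrix-class]
#' @return character vector of unique gene symbols
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Compound identifiers of a chemoactivity set
#' @param x a [ChemoProfileSet-class]
#' @return character vector of unique compound identifiers
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Has a chemoactivity set been two-stage normalized?
#' @param x a [ChemoProfileSet-class]
#' @return logical flag
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' Number of map nodes (grid cells) of a trained SOM
#' @param x a [SOMModel-class]
#' @return integer, always `somRows * somCols`
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Codebook matrix of a trained SOM
#'
#' One row per node (row-major, 0-based node indexing), one column per panel
#' cell line. Row `k + 1` holds the codebook ("SOM GI50") profile of node `k`.
#'
#' @param x a [SOMModel-class]
#' @return numeric matrix, `nNodes(x)` rows
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' Pathway names of a collection
#' @param x a [PathwayCollection-class]
#' @return character vector
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' Member gene sets of a pathway collection
#' @param x a [PathwayCollection-class]
#' @return named list of character vectors of gene symbols
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' H-score records as a data.frame
#' @param x a [HScoreTable-class]
#' @return data.frame with columns pathway, node, H, p, n_in, n_out,
#'   mean_r_in, mean_r_out
#' @export
setGeneric("hRecords", function(x) standardGeneric("hRecords"))
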