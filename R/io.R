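#' Read a tab-separated expression or chemoactivity matrix
#'
#' Expects a header row of cell ids and a first column of row keys (gene
#' symbols or compound ids). Empty cells and the literal token `NA` are
#' parsed as missing. Row keys must be unique; every data row must have
#' exactly as many fields as the header.
#'
#' @param path file path to a TSV matrix
#' @param kind `"expression"` or `"chemoactivity"`
#' @return an [ExpressionMatrix-class] or [ChemoProfileSet-class]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tC1\tC2\tC3", "g1\t1\t2\t3", "g2\t4\t\t6"), tf)
#' em <- readMatrix(tf, "expression")
#' exprValues(em)["g2", "C2"]  # NA: empty cell stays masked
#' @export
readMatrix <- function(path, kind = c("expression", "chemoactivity")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("matrix file needs a header and at least one data row: ", path)
  # sentinel keeps trailing empty fields (strsplit drops the final one)
  fields <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  ncol_head <- length(fields[[1L]])
  ragged <- which(lengths(fields)[-1L] != ncol_head) + 1L
  if (length(ragged))
    stop(sprintf("ragged row(s) at line %s: expected %d fields",
                 paste(ragged, collapse = ", "), ncol_head))
  cells <- trimws(fields[[1L]][-1L])
  keys <- vapply(fields[-1L], function(f) trimws(f[1L]), character(1))
  if (anyDuplicated(keys))
    stop("duplicate row key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  vals <- t(vapply(fields[-1L], function(f) {
    v <- trimws(f[-1L])
    v[v == "" | v == "NA"] <- NA
    suppressWarnings(as.numeric(v))
  }, numeric(length(cells))))
  dimnames(vals) <- list(keys, cells)
  if (kind == "expression") {
    few <- rowSums(!is.na(vals)) < 3L
    if (any(few) && ncol(vals) >= 3L)
      warning(sum(few), " gene(s) with < 3 non-missing values; their ",
              "correlations will be undefined")
    ExpressionMatrix(vals)
  } else {
    ChemoProfileSet(vals)
  }
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member
#' symbols within a line are collapsed; empty member fields are ignored.
#'
#' @param path GMT file path
#' @param source tag recorded for every set (e.g. `"KEGG"`)
#' @return a [PathwayCollection-class]
#' @export
readGMT <- function(path, source = "GMT") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT line %s has fewer than 3 fields",
                 paste(which(keep)[bad], collapse = ", ")))
  nm <- vapply(fields, function(f) trimws(f[1L]), character(1))
  if (anyDuplicated(nm))
    stop("duplicate pathway name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, function(f) trimws(f[2L]), character(1))
  sets <- lapply(fields, function(f) {
    g <- trimws(f[-(1:2)])
    unique(g[nzchar(g)])
  })
  names(sets) <- nm
  names(desc) <- nm
  PathwayCollection(sets, description = desc, source = source)
}

#' Write a pathway collection to GMT
#' @param x a [PathwayCollection-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(pathwayNames(x), function(nm) {
    paste(c(nm, x@description[[nm]], x@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a record table as deterministic TSV
#'
#' Column order follows the data.frame; numeric columns are formatted at 6
#' significant digits so reruns are byte-identical and the file re-reads to
#' the same values within 1e-6 relative tolerance.
#'
#' @param records a data.frame
#' @param path output path
#' @return invisibly, the path
#' @export
writeTable <- function(records, path) {
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6L)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a matrix-backed object to TSV (round-trippable by [readMatrix()])
#' @param x an [ExpressionMatrix-class] or [ChemoProfileSet-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeMatrix <- function(x, path) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else chemoValues(x)
  df <- data.frame(id = rownames(v), format(v, digits = 10, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("id", colnames(v))
  df[df == "NA"] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys keep the published defaults.
#' Keys use the snake_case spelling of the configuration fields
#' (`min_cells_reported`, `min_cv`, `som_rows`, `som_cols`, `som_epochs`,
#' `h_top_percentile`, `corr_alpha`, `trim_alpha`, `lda_folds`,
#' `min_overlap`, `max_iter`, `stage1`, `welch`, `conventional_mode`,
#' `conventional_value`, `rng_seed`).
#'
#' @param path a .yaml/.yml or .json file
#' @return a [RunConfig-class]
#' @export
readRunConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  key_map <- c(min_cells_reported = "minCellsReported", min_cv = "minCV",
               som_rows = "somRows", som_cols = "somCols",
               som_epochs = "somEpochs", h_top_percentile = "hTopPercentile",
               corr_alpha = "corrAlpha", trim_alpha = "trimAlpha",
               lda_folds = "ldaFolds", min_overlap = "minOverlap",
               max_iter = "maxIter", stage1 = "stage1", welch = "welch",
               conventional_mode = "conventionalMode",
               conventional_value = "conventionalValue", rng_seed = "rngSeed")
  unknown <- setdiff(names(vals), names(key_map))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(vals, key_map[names(vals)])
  do.call(runConfig, args)
}
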