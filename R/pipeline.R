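#' Serialize a trained SOM to JSON
#' @param model a [SOMModel-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeSOMModel <- function(model, path) {
  jsonlite::write_json(list(
    rows = model@rows, cols = model@cols, seed = model@seed,
    train_params = model@trainParams, cell_ids = cellIds(model),
    qe_log = model@qeLog,
    codebook = unname(apply(codebook(model), 1L, identity, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON-serialized SOM
#' @param path path written by [writeSOMModel()]
#' @return a [SOMModel-class]
#' @export
readSOMModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- if (is.matrix(j$codebook)) j$codebook
  else matrix(unlist(j$codebook), nrow = j$rows * j$cols, byrow = TRUE)
  colnames(cb) <- j$cell_ids
  new("SOMModel", rows = as.integer(j$rows), cols = as.integer(j$cols),
      codebook = cb, trainParams = as.list(j$train_params),
      seed = as.integer(j$seed), qeLog = as.numeric(j$qe_log))
}

#' Serialize a discriminant set to JSON
#' @param set a [DiscriminantSet-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeDiscriminantSet <- function(set, path) {
  jsonlite::write_json(list(
    status = set@status, converged = set@converged,
    iterations = set@nIterations,
    genes = data.frame(gene = set@genes, class = set@geneClass,
                       r = set@geneR, p = set@geneP),
    cells = data.frame(cell = set@cells, class = set@cellClass,
                       chemoactivity = set@cellChemo, p = set@cellP)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.configSnapshot <- function(config) {
  sl <- slotNames(config)
  stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

.digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full mining workflow
#'
#' Orchestrates simulate -> normalize -> som -> hscore -> discriminate ->
#' enrich on a directory of TSV/GMT artifacts, writing a JSON run manifest
#' (config snapshot, seed, stage timings, input/output digests, status).
#' With `simulate = TRUE` the synthetic generator first writes `E.tsv`,
#' `C.tsv` and `P.gmt` into `out`; otherwise those files must already be
#' there (copy or point your own inputs). Re-runs skip a stage when its
#' recorded input digests are unchanged and its outputs exist, unless
#' `force = TRUE`. A failing stage halts everything downstream and is
#' recorded in the manifest.
#'
#' @param out output directory (created if needed)
#' @param config a [RunConfig-class]
#' @param stages subset of
#'   `c("simulate", "normalize", "som", "hscore", "discriminate", "enrich")`
#' @param simulate generate synthetic inputs first
#' @param simArgs list of overrides passed to [generatePanel()]
#' @param force re-run stages even when inputs are unchanged
#' @return the manifest, invisibly (also written to `out/manifest.json`)
#' @export
runPipeline <- function(out, config = runConfig(),
                        stages = c("simulate", "normalize", "som", "hscore",
                                   "discriminate", "enrich"),
                        simulate = "simulate" %in% stages,
                        simArgs = list(), force = FALSE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  p <- function(f) file.path(out, f)
  manifestPath <- p("manifest.json")
  prev <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
  manifest <- list(config = .configSnapshot(config), seed = config@rngSeed,
                   stages = list())
  halted <- FALSE

  stageIO <- list(
    simulate = list(inputs = character(),
                    outputs = c("E.tsv", "C.tsv", "P.gmt", "truth.json")),
    normalize = list(inputs = c("E.tsv", "C.tsv", "P.gmt"),
                     outputs = c("norm_C.tsv", "filtered_E.tsv",
                                 "filtered_P.gmt", "filter_report.json")),
    som = list(inputs = "norm_C.tsv", outputs = "som.json"),
    hscore = list(inputs = c("filtered_E.tsv", "som.json",
                             "filtered_P.gmt"),
                  outputs = "hscores.tsv"),
    discriminate = list(inputs = c("hscores.tsv", "filtered_E.tsv",
                                   "som.json"),
                        outputs = "discriminant_sets.json"),
    enrich = list(inputs = c("discriminant_sets.json", "filtered_P.gmt",
                             "filtered_E.tsv"),
                  outputs = "enrichment.tsv"))

  runStage <- function(name, fun) {
    io <- stageIO[[name]]
    rec <- list(status = "skipped", inputs = .digests(p(io$inputs)))
    if (halted) {
      rec$status <- "halted"
    } else {
      prevRec <- prev$stages[[name]]
      unchanged <- !force && !is.null(prevRec) &&
        isTRUE(prevRec$status %in% c("done", "skipped")) &&
        identical(as.list(prevRec$inputs), rec$inputs) &&
        all(file.exists(p(io$outputs)))
      if (!unchanged) {
        t0 <- proc.time()[["elapsed"]]
        ok <- tryCatch({ fun(); TRUE },
                       error = function(e) {
                         rec$error <<- conditionMessage(e); FALSE
                       })
        rec$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
        rec$status <- if (ok) "done" else "failed"
        if (!ok) halted <<- TRUE
      }
    }
    rec$outputs <- .digests(p(io$outputs))
    manifest$stages[[name]] <<- rec
  }

  if ("simulate" %in% stages && simulate)
    runStage("simulate", function() {
      sim <- do.call(generatePanel, utils::modifyList(
        list(seed = config@rngSeed), simArgs))
      writeMatrix(sim$expr, p("E.tsv"))
      writeMatrix(sim$chemo, p("C.tsv"))
      writeGMT(sim$pathways, p("P.gmt"))
      jsonlite::write_json(sim$truth[c("plantedPathways", "sensitiveCells",
                                       "clusterOf", "noiseSd", "effectSize",
                                       "seed")],
                           p("truth.json"), auto_unbox = TRUE, digits = NA)
    })

  if ("normalize" %in% stages)
    runStage("normalize", function() {
      chemo <- readMatrix(p("C.tsv"), "chemoactivity")
      expr <- readMatrix(p("E.tsv"), "expression")
      gmt <- readGMT(p("P.gmt"))
      # synthetic desk-scale panels have fewer cells than the published
      # coverage rule; the rule caps at panel size - 1 so it stays strict
      minCells <- min(config@minCellsReported, ncol(chemo) - 1L)
      fc <- filterChemoProfiles(chemo, minCells, config@minCV)
      norm <- normalizeChemo(fc$profiles, config@stage1)
      fe <- filterExpressionGenes(expr, gmt, config@minCV)
      fp <- filterPathways(gmt, fe)
      writeMatrix(norm, p("norm_C.tsv"))
      writeMatrix(fe, p("filtered_E.tsv"))
      writeGMT(fp, p("filtered_P.gmt"))
      jsonlite::write_json(as.list(fc$report), p("filter_report.json"),
                           auto_unbox = TRUE, digits = NA)
    })

  if ("som" %in% stages)
    runStage("som", function() {
      norm <- readMatrix(p("norm_C.tsv"), "chemoactivity")
      norm@normalized <- TRUE
      model <- trainSOM(norm, config)
      writeSOMModel(model, p("som.json"))
    })

  if ("hscore" %in% stages)
    runStage("hscore", function() {
      expr <- readMatrix(p("filtered_E.tsv"), "expression")
      model <- readSOMModel(p("som.json"))
      pw <- readGMT(p("filtered_P.gmt"))
      corr <- geneNodeCorrelations(expr, model)
      tab <- hScoreTable(corr, pw)
      writeTable(hRecords(tab), p("hscores.tsv"))
    })

  if ("discriminate" %in% stages)
    runStage("discriminate", function() {
      expr <- readMatrix(p("filtered_E.tsv"), "expression")
      model <- readSOMModel(p("som.json"))
      pw <- readGMT(p("filtered_P.gmt"))
      norm <- readMatrix(p("norm_C.tsv"), "chemoactivity")
      rec <- utils::read.delim(p("hscores.tsv"))
      rec$node <- as.character(rec$node)
      tab <- new("HScoreTable", records = rec)
      nodes <- sort(unique(assignNode(model, {
        norm@normalized <- TRUE; norm
      })))
      sets <- lapply(nodes, function(nd) {
        prof <- codebookProfile(model, nd)
        pool <- candidatePool(nd, tab, expr, prof, pw, config)
        ds <- trimDiscriminant(pool, expr, prof, config)
        list(node = nd, status = ds@status, converged = ds@converged,
             iterations = ds@nIterations,
             genes = data.frame(gene = ds@genes, class = ds@geneClass,
                                r = ds@geneR, p = ds@geneP),
             cells = data.frame(cell = ds@cells, class = ds@cellClass,
                                p = ds@cellP))
      })
      jsonlite::write_json(sets, p("discriminant_sets.json"),
                           auto_unbox = TRUE, digits = NA)
    })

  if ("enrich" %in% stages)
    runStage("enrich", function() {
      expr <- readMatrix(p("filtered_E.tsv"), "expression")
      pw <- readGMT(p("filtered_P.gmt"))
      sets <- jsonlite::read_json(p("discriminant_sets.json"))
      reports <- lapply(sets, function(s) {
        genes <- vapply(s$genes, function(g) g$gene, character(1))
        if (length(genes) < 1L) return(NULL)
        r <- enrichmentReport(genes, pw, geneIds(expr), config)
        if (nrow(r)) cbind(node = s$node, r) else NULL
      })
      reports <- do.call(rbind, reports)
      if (is.null(reports))
        reports <- data.frame(node = integer(), name = character(),
                              p = numeric())
      writeTable(reports, p("enrichment.tsv"))
    })

  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
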