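# Shared fixtures, built in code. The full synthetic pipeline fixture is
# cached per test run since several files exercise different stages of the
# same panel.

.fixtureCache <- new.env(parent = emptyenv())

# A small trained pipeline on the default synthetic preset: panel, filtered
# objects, SOM (6x5 grid: desk-scale analog of the production map),
# assignments and H-score table.
pipelineFixture <- function(seed = 2L) {
  key <- paste0("pipe", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  cfg <- runConfig(somRows = 6L, somCols = 5L, somEpochs = 30L,
                   rngSeed = seed)
  sim <- generatePanel(seed = seed)
  norm <- normalizeChemo(filterChemoProfiles(sim$chemo, 40, 0.05)$profiles)
  fe <- filterExpressionGenes(sim$expr, sim$pathways, 0.05)
  fp <- filterPathways(sim$pathways, fe)
  model <- trainSOM(norm, cfg)
  assignments <- assignNode(model, norm)
  tab <- hScoreTable(geneNodeCorrelations(fe, model), fp)
  fx <- list(cfg = cfg, sim = sim, norm = norm, expr = fe, pathways = fp,
             model = model, assignments = assignments, tab = tab)
  .fixtureCache[[key]] <- fx
  fx
}

# Modal SOM node of a planted compound cluster.
clusterNode <- function(fx, cluster) {
  a <- fx$assignments
  memb <- a[fx$sim$truth$clusterOf[names(a)] == cluster]
  as.integer(names(which.max(table(memb))))
}

# A converged discriminant set for one cluster of the pipeline fixture.
clusterDiscriminantSet <- function(fx, cluster = 1L) {
  nd <- clusterNode(fx, cluster)
  prof <- codebookProfile(fx$model, nd)
  pool <- candidatePool(nd, fx$tab, fx$expr, prof, fx$pathways, fx$cfg)
  list(node = nd, profile = prof, pool = pool,
       set = trimDiscriminant(pool, fx$expr, prof, fx$cfg))
}

# Perfect block design: over-genes high exactly in sensitive cells, no
# noise. Returns expression, chemo profile and the pool data.frame.
blockDesign <- function(nGenes = 10L, nCells = 20L, delta = 2) {
  cells <- sprintf("c%02d", seq_len(nCells))
  genes <- sprintf("g%02d", seq_len(nGenes))
  sens <- rep(c(TRUE, FALSE), each = nCells / 2)
  base <- seq(-0.4, 0.4, length.out = nCells)  # within-class spread
  E <- matrix(rep(base, each = nGenes), nGenes, nCells,
              dimnames = list(genes, cells))
  sgn <- rep(c(1, -1), length.out = nGenes)    # over_sensitive / over_insensitive
  E <- E + (sgn %o% ifelse(sens, 1, -1)) * delta / 2
  chemo <- stats::setNames(ifelse(sens, 1, -1) + base / 10, cells)
  pool <- data.frame(
    gene = genes,
    r = vapply(genes, function(g) stats::cor(E[g, ], chemo), numeric(1)),
    p = 1e-6)
  pool <- pool[order(pool$r, pool$gene), ]
  list(expr = ExpressionMatrix(E), chemo = chemo, pool = pool, sens = sens)
}

# Independent brute-force Kruskal-Wallis (midranks + explicit tie
# correction), written directly from the defining formula.
bruteKW <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x, ties.method = "average")
  m <- (N + 1) / 2
  num <- 0
  i <- 0L
  for (g in groups) {
    rg <- rk[i + seq_along(g)]
    num <- num + length(g) * (mean(rg) - m)^2
    i <- i + length(g)
  }
  H0 <- 12 / (N * (N + 1)) * num
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) 0 else H0 / corr
}
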