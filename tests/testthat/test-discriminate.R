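test_that("candidate pools keep only significantly correlated pathway genes", {
  fx <- pipelineFixture()
  d <- clusterDiscriminantSet(fx, 1L)
  pool <- d$pool
  expect_gt(nrow(pool), 0)
  expect_true(all(pool$p < fx$cfg@corrAlpha))
  expect_false(anyDuplicated(pool$gene) > 0)
  # ordered most negative correlation first
  expect_identical(pool$r, sort(pool$r))
  # every pool gene belongs to a top-decile pathway at that node
  top <- topPercentilePathways(fx$tab, d$node, 10)
  members <- unique(unlist(geneSets(fx$pathways)[top]))
  expect_true(all(pool$gene %in% members))
})

test_that("the r-to-p transform gates pool membership as a t statistic", {
  # r = 0.9 at n = 20 gives t = r sqrt(18 / (1 - r^2)) = 8.76, p << 0.05
  p <- chemopath:::.corPValue(0.9, 20L)
  t <- 0.9 * sqrt(18 / (1 - 0.81))
  expect_equal(t, 8.76, tolerance = 1e-3)
  expect_equal(p, 2 * pt(-t, 18), tolerance = 1e-12)
  expect_lt(p, 1e-7)

  # a weakly correlated gene in a top pathway is excluded
  cells <- sprintf("c%02d", 1:20)
  set.seed(21)
  prof <- setNames(rnorm(20), cells)
  strong <- 0.95 * scale(prof)[, 1] + 0.1 * rnorm(20)
  weak <- rnorm(20)
  E <- rbind(gStrong = strong, gWeak = weak)
  colnames(E) <- cells
  pw <- PathwayCollection(list(TOP = c("gStrong", "gWeak")))
  pool <- poolGenes("TOP", pw, ExpressionMatrix(E), prof, runConfig())
  expect_true("gStrong" %in% pool$gene)
  expect_false("gWeak" %in% pool$gene)
})

test_that("a perfect block design is separable in a single pass", {
  bd <- blockDesign()
  ds <- trimDiscriminant(bd$pool, bd$expr, bd$chemo, runConfig())
  expect_identical(ds@status, "ok")
  expect_true(ds@converged)
  expect_identical(ds@nIterations, 1L)
  expect_setequal(ds@genes, bd$pool$gene)
  expect_identical(length(ds@cells), 20L)
  expect_true(all(ds@geneP < 0.05, na.rm = TRUE))
  expect_true(all(ds@cellP < 0.05, na.rm = TRUE))
})

test_that("pure-noise genes are trimmed away while planted genes survive", {
  nSeeds <- 20
  kept <- t(vapply(seq_len(nSeeds), function(s) {
    set.seed(s)
    bd <- blockDesign(nGenes = 12L, nCells = 24L)
    E <- exprValues(bd$expr)
    noise <- matrix(rnorm(5 * ncol(E)), 5, ncol(E),
                    dimnames = list(sprintf("noise%d", 1:5), colnames(E)))
    E2 <- rbind(E, noise)
    rn <- vapply(rownames(noise), function(g)
      cor(noise[g, ], bd$chemo), numeric(1))
    pool <- rbind(bd$pool,
                  data.frame(gene = rownames(noise), r = rn, p = 0.04))
    ds <- trimDiscriminant(pool, ExpressionMatrix(E2), bd$chemo, runConfig())
    c(planted = sum(bd$pool$gene %in% ds@genes) / nrow(bd$pool),
      noise = sum(rownames(noise) %in% ds@genes) / 5)
  }, numeric(2)))
  # a 0.05 nominal test lets the occasional noise gene through; in
  # aggregate at least 90% of noise is removed and 90% of signal kept
  expect_gte(mean(kept[, "planted"]), 0.9)
  expect_lte(mean(kept[, "noise"]), 0.1)
})

test_that("trimming is invariant to gene and cell input order", {
  fx <- pipelineFixture()
  d <- clusterDiscriminantSet(fx, 2L)
  pool <- d$pool
  E <- exprValues(fx$expr)
  set.seed(33)
  poolPerm <- pool[sample(nrow(pool)), ]
  exprPerm <- ExpressionMatrix(E[, sample(ncol(E))])
  ds1 <- d$set
  ds2 <- trimDiscriminant(poolPerm, exprPerm, d$profile, fx$cfg)
  expect_identical(ds1@genes, ds2@genes)
  expect_identical(ds1@cells, ds2@cells)
  expect_identical(ds1@geneClass, ds2@geneClass)
})

test_that("trimming terminates within its structural bound", {
  fx <- pipelineFixture()
  for (cl in 1:4) {
    d <- clusterDiscriminantSet(fx, cl)
    expect_lte(d$set@nIterations,
               nrow(d$pool) + length(cellIds(fx$expr)))
  }
})

test_that("tightening the trim threshold never grows the gene set", {
  fx <- pipelineFixture()
  d <- clusterDiscriminantSet(fx, 1L)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  counts <- vapply(alphas, function(a) {
    cfg <- fx$cfg; cfg@trimAlpha <- a
    length(trimDiscriminant(d$pool, fx$expr, d$profile, cfg)@genes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("four-class labels partition the grid into the Fig-3 quadrants", {
  bd <- blockDesign()
  ds <- trimDiscriminant(bd$pool, bd$expr, bd$chemo, runConfig())
  lab <- fourClassLabels(ds)
  expect_identical(dim(lab), c(length(ds@genes), length(ds@cells)))
  expect_true(all(lab %in% c("A", "B", "C", "D")))
  cnt <- table(factor(lab, c("A", "B", "C", "D")))
  expect_identical(sum(cnt), length(lab))
  nNeg <- sum(ds@geneClass == "over_insensitive")
  nIns <- sum(ds@cellClass == "insensitive")
  expect_identical(unname(cnt[["A"]]), nNeg * nIns)

  # over-expressed quadrants carry the higher expression
  E <- exprValues(bd$expr)[ds@genes, ds@cells]
  mA <- mean(E[lab == "A"]); mB <- mean(E[lab == "B"])
  mC <- mean(E[lab == "C"]); mD <- mean(E[lab == "D"])
  expect_gt(mA, mB); expect_gt(mA, mC)
  expect_gt(mD, mB); expect_gt(mD, mC)
})

test_that("failure modes are reported, not crashed", {
  empty <- data.frame(gene = character(), r = numeric(), p = numeric())
  fx <- pipelineFixture()
  ds <- trimDiscriminant(empty, fx$expr, codebookProfile(fx$model, 0),
                         fx$cfg)
  expect_identical(ds@status, "empty pool")
  expect_false(ds@converged)

  # all candidate genes on one side: the other class empties by name
  bd <- blockDesign()
  onesided <- bd$pool[bd$pool$r > 0, ]
  ds2 <- trimDiscriminant(onesided, bd$expr, bd$chemo, runConfig())
  expect_match(ds2@status, "over_insensitive")
})

test_that("shuffle-null false positives are far below the nominal level", {
  fx <- pipelineFixture()
  d <- clusterDiscriminantSet(fx, 1L)
  expect_error(shuffleNullFPR(d$set, fx$expr, fx$cfg, nPerm = 50),
               "nPerm")
  sn <- shuffleNullFPR(d$set, fx$expr, fx$cfg, nPerm = 2000L)
  expect_gte(sn$n_shuffled, 2000L)
  expect_lte(sn$fpr, fx$cfg@trimAlpha)

  # sanity: the unshuffled set re-passes its own tests wholesale
  E <- exprValues(fx$expr)[d$set@genes, d$set@cells, drop = FALSE]
  res <- chemopath:::.trimLoop(E, d$set@geneClass,
                               d$set@cellClass == "sensitive",
                               fx$cfg@trimAlpha, FALSE, 100L)
  expect_true(res$converged)
  expect_true(all(res$gkeep))
  expect_true(all(res$ckeep))
})
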