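sepClouds <- function(n = 30, p = 4, gap = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%d", 1:p), sprintf("c%02d", 1:n)))
  X[1, y] <- X[1, y] + gap
  list(X = X, y = y)
}

test_that("LDA accuracy: separable clouds, shuffled labels, LOO oracle", {
  sc <- sepClouds()
  expect_equal(ldaCvAccuracy(sc$X, sc$y, k = 5, seed = 1), 1.0)

  # label shuffles land at chance within binomial error
  set.seed(9)
  accs <- replicate(20, ldaCvAccuracy(sc$X, sample(sc$y), k = 5,
                                      seed = sample(1e4, 1)))
  expect_lt(abs(mean(accs) - 0.5), 3 / sqrt(20 * ncol(sc$X)) + 0.05)

  # k = n reproduces an explicit leave-one-out loop over the same
  # classifier
  sc2 <- sepClouds(n = 16, gap = 2.2, seed = 3)
  n <- ncol(sc2$X)
  loo <- vapply(seq_len(n), function(i) {
    fit <- chemopath:::.fisherLDA(sc2$X[, -i, drop = FALSE], sc2$y[-i])
    chemopath:::.fisherPredict(fit, sc2$X[, i, drop = FALSE]) == sc2$y[i]
  }, logical(1))
  expect_equal(ldaCvAccuracy(sc2$X, sc2$y, k = n, seed = 5), mean(loo))
})

test_that("the Fisher direction matches MASS::lda where both are defined", {
  sc <- sepClouds(n = 40, p = 3, gap = 2, seed = 7)
  fit <- chemopath:::.fisherLDA(sc$X, sc$y)
  ref <- MASS::lda(t(sc$X), grouping = factor(sc$y),
                   prior = c(0.5, 0.5))
  wRef <- ref$scaling[, 1]
  cosang <- abs(sum(fit$w * wRef)) /
    sqrt(sum(fit$w^2) * sum(wRef^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
  # and predictions agree
  mine <- chemopath:::.fisherPredict(fit, sc$X)
  theirs <- predict(ref, t(sc$X))$class == "TRUE"
  expect_identical(mine, unname(theirs))
})

test_that("LDA still returns on p >> n separable panels and ignores column order", {
  set.seed(13)
  n <- 14; p <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%02d", 1:p), sprintf("c%02d", 1:n)))
  X[1:10, y] <- X[1:10, y] + 3
  acc <- ldaCvAccuracy(X, y, k = 5, seed = 2)
  expect_gte(acc, 0.8)

  perm <- sample(n)
  expect_equal(ldaCvAccuracy(X[, perm], y[perm], k = 5, seed = 2), acc)
})

test_that("conventional selection cuts by alpha or percentile as declared", {
  set.seed(17)
  cells <- sprintf("c%02d", 1:30)
  prof <- setNames(rnorm(30), cells)
  E <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(sprintf("g%03d", 1:100), cells))
  E[1:5, ] <- E[1:5, ] + 2 * matrix(rep(prof, each = 5), 5)
  em <- ExpressionMatrix(E)

  top10 <- conventionalSelection(em, prof, "percentile", 10)
  expect_identical(nrow(top10), 10L)

  byAlpha <- conventionalSelection(em, prof, "alpha", 0.05)
  rn <- chemopath:::.corAgainstProfile(E, prof)
  pv <- chemopath:::.corPValue(rn$r, rn$n)
  expect_setequal(byAlpha$gene, rownames(E)[!is.na(pv) & pv < 0.05])
})

test_that("method comparison: noise-free panels are perfectly predictable", {
  sim <- generatePanel(noiseSd = 1e-6, missingRate = 0, seed = 12)
  cfg <- runConfig(somRows = 3, somCols = 3, somEpochs = 30, rngSeed = 6)
  norm <- normalizeChemo(filterChemoProfiles(sim$chemo, 40, 0.05)$profiles)
  fe <- filterExpressionGenes(sim$expr, sim$pathways, 0.05)
  fp <- filterPathways(sim$pathways, fe)
  m <- trainSOM(norm, cfg)
  a <- assignNode(m, norm)
  tab <- hScoreTable(geneNodeCorrelations(fe, m), fp)
  mc <- methodComparison(fe, fp, m, tab, unique(a), cfg, seed = 6,
                         exprAll = sim$expr)
  expect_identical(mc$n_failed, 0L)
  # trimmed arms are perfectly separable; untrimmed arms keep every panel
  # cell, including the occasional cell whose normalized-profile sign
  # disagrees with its planted expression pattern
  s <- mc$summary
  expect_true(all(s$mean_accuracy[s$trimming == "trimmed"] == 1))
  expect_true(all(s$mean_accuracy[s$trimming == "untrimmed"] >= 0.9))
  # trimming only removes genes
  for (u in mc$units) {
    expect_lte(u$pathway_trimmed[["genes"]], u$pathway_untrimmed[["genes"]])
    expect_lte(u$conventional_trimmed[["genes"]],
               u$conventional_untrimmed[["genes"]])
  }
})

test_that("top-pathway concordance: identical profiles give full overlap", {
  fx <- pipelineFixture()
  # a chemo set whose profiles are exactly codebook rows of occupied nodes
  occ <- sort(unique(fx$assignments))[1:3]
  cb <- codebook(fx$model)[occ + 1L, , drop = FALSE]
  rownames(cb) <- sprintf("copy%d", seq_along(occ))
  fakeAssign <- setNames(occ, rownames(cb))
  cc <- pathwayOverlapConcordance(fx$model, fx$expr, ChemoProfileSet(cb),
                                  fakeAssign, fx$pathways, fx$cfg,
                                  nNodesSample = 3, membersPerNode = 2,
                                  seed = 4)
  expect_equal(cc$mean, 1.0)

  # unrelated noise profiles overlap only at the random-expectation scale
  set.seed(5)
  noise <- matrix(rnorm(length(cb)), nrow(cb),
                  dimnames = dimnames(cb))
  ccN <- pathwayOverlapConcordance(fx$model, fx$expr,
                                   ChemoProfileSet(noise), fakeAssign,
                                   fx$pathways, fx$cfg, nNodesSample = 3,
                                   membersPerNode = 2, seed = 4)
  expect_lt(ccN$mean, 0.6)

  # the real panel sits clearly above the noise floor
  ccR <- pathwayOverlapConcordance(fx$model, fx$expr, fx$norm,
                                   fx$assignments, fx$pathways, fx$cfg,
                                   nNodesSample = 10, membersPerNode = 5,
                                   seed = 4)
  expect_gt(ccR$mean, ccN$mean)
  expect_true(all(ccR$fractions >= 0 & ccR$fractions <= 1))
})

test_that("white-noise degradation hits its correlation target and shrinks sets", {
  fx <- pipelineFixture()
  d <- clusterDiscriminantSet(fx, 1L)
  nd <- noiseDegradation(fx$expr, target = 0.6, node = d$node,
                         hTable = fx$tab, pathways = fx$pathways,
                         chemoProfile = d$profile, config = fx$cfg,
                         seed = 19, baseline = d$set)
  expect_lte(abs(nd$achieved - 0.6), 0.02)
  expect_gt(nd$sigma, 0)
  # noise attenuates every gene-profile correlation, so the pool of
  # significantly correlated candidates shrinks; the post-trim count on a
  # small panel also depends on how many noisy cells the trim removes, so
  # only the pool contraction is asserted strictly
  expect_lt(nd$pool_ratio, 1)
  expect_identical(nd$baseline_genes, length(d$set@genes))
  expect_true(is.finite(nd$ratio) && nd$ratio > 0)
})

test_that("expression degradation: identity at zero, monotone decorrelation", {
  fx <- pipelineFixture()
  expect_identical(exprValues(degradeExpression(fx$expr, 0)),
                   exprValues(fx$expr))
  E <- exprValues(fx$expr)
  meanCor <- vapply(c(0.5, 1, 2), function(s) {
    D <- exprValues(degradeExpression(fx$expr, s, seed = 3))
    expect_identical(is.na(D), is.na(E))  # masks preserved
    mean(vapply(seq_len(nrow(E)), function(i)
      suppressWarnings(cor(E[i, ], D[i, ], use = "pairwise.complete.obs")),
      numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meanCor) < 0))
})
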