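test_that("masked Pearson correlation handles identity, inversion, ties, masks", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonMasked(x, x)$r, 1)
  expect_equal(pearsonMasked(x, -x)$r, -1)
  expect_equal(pearsonMasked(x, c(2, 1, 4, 3))$r, 0.6)  # hand: cov 1, sd 5/3

  got <- pearsonMasked(c(1, 2, NA, 4, 5), c(2, NA, 3, 8, 10))
  expect_identical(got$n, 3L)
  expect_equal(got$r, cor(c(1, 4, 5), c(2, 8, 10)))

  expect_true(is.na(pearsonMasked(c(1, 2, NA, NA), c(1, NA, 2, 3))$r))
  expect_true(is.na(pearsonMasked(c(1, 1, 1, 1), x)$r))  # zero variance
})

test_that("gene-node correlations match looped masked Pearson calls", {
  fx <- pipelineFixture()
  corr <- geneNodeCorrelations(fx$expr, fx$model)
  expect_identical(dim(corr$r),
                   c(length(geneIds(fx$expr)), nNodes(fx$model)))
  E <- exprValues(fx$expr)
  cb <- codebook(fx$model)
  set.seed(1)
  for (i in sample(nrow(E), 20)) {
    j <- sample(nrow(cb), 1)
    expect_equal(corr$r[i, j], pearsonMasked(E[i, ], cb[j, ])$r,
                 tolerance = 1e-12)
  }

  # a gene equal to a codebook profile correlates perfectly at that node
  v <- rbind(E, SELFPROBE = cb[3, ])
  corr2 <- geneNodeCorrelations(ExpressionMatrix(v), fx$model)
  expect_equal(corr2$r["SELFPROBE", 3], 1)

  wrong <- ExpressionMatrix(E[, rev(colnames(E))])
  expect_error(geneNodeCorrelations(wrong, fx$model), "panel")
})

test_that("two-group Kruskal-Wallis matches hand and brute-force computation", {
  kw <- kruskalWallisH(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)   # 12/42 * (3*1.5^2 * 2)
  expect_equal(kw$p, pchisq(27 / 7, 1, lower.tail = FALSE))

  # interleaved identical distributions carry no real signal
  kwI <- kruskalWallisH(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_lt(kwI$H, 0.5)
  expect_gt(kwI$p, 0.5)

  # complete tie degenerates to H = 0, p = 1
  expect_identical(kruskalWallisH(c(2, 2), c(2, 2, 2)), list(H = 0, p = 1))

  set.seed(42)
  for (i in 1:1000) {
    na <- sample(2:10, 1); nb <- sample(2:10, 1)
    pool <- if (i %% 2) rnorm(na + nb) else sample(1:5, na + nb, TRUE)
    a <- pool[seq_len(na)]; b <- pool[na + seq_len(nb)]
    expect_equal(kruskalWallisH(a, b)$H, bruteKW(list(a, b)),
                 tolerance = 1e-9)
  }
})

test_that("H agrees with stats::kruskal.test and the squared rank-sum z", {
  set.seed(7)
  for (i in 1:50) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    pool <- if (i %% 3) rnorm(na + nb) else sample(1:6, na + nb, TRUE)
    a <- pool[seq_len(na)]; b <- pool[na + seq_len(nb)]
    H <- kruskalWallisH(a, b)$H
    ref <- suppressWarnings(
      kruskal.test(list(a, b))$statistic)
    expect_equal(H, unname(ref), tolerance = 1e-9)

    # two-group identity: H equals the squared standardized Wilcoxon
    # rank-sum statistic with tie correction
    N <- na + nb
    rk <- rank(c(a, b))
    W <- sum(rk[seq_len(na)])
    EW <- na * (N + 1) / 2
    VW <- na * nb / (N * (N - 1)) * (sum(rk^2) - N * (N + 1)^2 / 4)
    if (VW > 0)
      expect_equal(H, (W - EW)^2 / VW, tolerance = 1e-9)
  }
})

test_that("pathwayH: sign symmetry, extremal membership, degenerate input", {
  set.seed(3)
  rcol <- setNames(runif(8, -1, 1), paste0("g", 1:8))
  memb <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  h1 <- pathwayH(rcol, memb)
  h2 <- pathwayH(rcol, !memb)
  expect_equal(h1$H, -h2$H, tolerance = 1e-12)
  expect_equal(abs(h1$H), abs(h2$H))

  # members on the top-3 correlation strengths maximise H over all C(8,3)
  # placements, with positive sign
  strengths <- abs(rcol)
  topIdx <- order(strengths, decreasing = TRUE)[1:3]
  combos <- combn(8, 3)
  Hs <- apply(combos, 2, function(ix)
    pathwayH(rcol, seq_len(8) %in% ix)$H)
  best <- pathwayH(rcol, seq_len(8) %in% topIdx)
  expect_equal(best$H, max(Hs))
  expect_gt(best$H, 0)

  # fewer than two defined member correlations invalidates the record
  rcol2 <- rcol; rcol2[1:2] <- NA
  expect_false(pathwayH(rcol2, memb)$valid)
  expect_true(pathwayH(rcol, memb)$valid)
})

test_that("random membership keeps the nominal false-positive rate", {
  set.seed(11)
  rcol <- setNames(rnorm(200) / 3, paste0("g", 1:200))
  hits <- replicate(1000, {
    memb <- seq_len(200) %in% sample(200, 10)
    pathwayH(rcol, memb)$p < 0.05
  })
  rate <- mean(hits)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("the H-score table is complete, consistent and truth-recovering", {
  fx <- pipelineFixture()
  rec <- hRecords(fx$tab)
  expect_identical(nrow(rec),
                   length(fx$pathways) * nNodes(fx$model))

  # sign invariant on every valid record, exactly
  v <- rec[rec$valid, ]
  expect_true(all(sign(v$H) == sign(v$mean_r_in - v$mean_r_out) | v$H == 0))

  # spot-check table rows against direct pathwayH calls
  corr <- geneNodeCorrelations(fx$expr, fx$model)
  set.seed(2)
  for (k in sample(nrow(v), 10)) {
    row <- v[k, ]
    direct <- pathwayH(corr$r[, as.character(row$node)],
                       geneSets(fx$pathways)[[row$pathway]])
    expect_equal(row$H, direct$H, tolerance = 1e-9)
    expect_equal(row$p, direct$p, tolerance = 1e-9)
    expect_identical(row$n_in, direct$n_in)
  }

  # noiseless planted pathway dominates its cluster's node
  sim0 <- generatePanel(noiseSd = 1e-6, missingRate = 0, seed = 8)
  norm0 <- normalizeChemo(filterChemoProfiles(sim0$chemo, 40, 0.05)$profiles)
  fe0 <- filterExpressionGenes(sim0$expr, sim0$pathways, 0.05)
  fp0 <- filterPathways(sim0$pathways, fe0)
  m0 <- trainSOM(norm0, runConfig(somRows = 3, somCols = 3, somEpochs = 30,
                                  rngSeed = 4))
  a0 <- assignNode(m0, norm0)
  tab0 <- hScoreTable(geneNodeCorrelations(fe0, m0), fp0)
  planted <- unname(sim0$truth$plantedPathways)
  for (c_ in 1:4) {
    cl <- a0[sim0$truth$clusterOf[names(a0)] == c_]
    nd <- names(which.max(table(cl)))
    r0 <- hRecords(tab0)
    r0 <- r0[r0$node == nd & r0$valid, ]
    own <- r0$H[r0$pathway == planted[c_]]
    # the cluster's own pathway beats every background pathway outright
    # (other planted pathways also score via the cross-cluster component
    # the across-cell normalization introduces, so "best overall" is not
    # the right noiseless truth statement)
    expect_gt(own, max(r0$H[!(r0$pathway %in% planted)]))
    expect_true(planted[c_] %in% topPercentilePathways(tab0, nd, 10))
  }
})

test_that("top-percentile selection uses the inclusive ceil rule", {
  mk <- function(H) new("HScoreTable", records = data.frame(
    pathway = sprintf("P%02d", seq_along(H)), node = "0", H = H,
    p = rep(0.5, length(H)), n_in = 2L, n_out = 5L,
    mean_r_in = H, mean_r_out = 0, valid = TRUE))
  # ten pathways at percentile 10: exactly the single best
  t1 <- mk(c(5, 3, 8, 1, 2, 7, 4, 6, 0.5, 2.5))
  expect_identical(topPercentilePathways(t1, 0, 10), "P03")
  # complete tie returns everything
  t2 <- mk(rep(2, 6))
  expect_identical(topPercentilePathways(t2, 0, 10),
                   sprintf("P%02d", 1:6))
  # brute-force sort-and-cut oracle on random tables
  set.seed(5)
  for (i in 1:20) {
    H <- round(rnorm(sample(5:30, 1)), 2)
    pct <- sample(c(10, 20, 35), 1)
    got <- topPercentilePathways(mk(H), 0, pct)
    k <- ceiling(pct / 100 * length(H))
    cut <- sort(H, decreasing = TRUE)[k]
    want <- sprintf("P%02d", which(H >= cut))
    expect_setequal(got, want)
    expect_identical(got, got[order(-H[match(got, sprintf("P%02d",
                                                          seq_along(H)))],
                                    got)])
  }
})
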