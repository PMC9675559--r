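# cohort with two strongly coexpressed planted modules and noise genes
plantedModuleExpr <- function(nPerModule = 10, nNoise = 0, nSamples = 40,
                              signal = 4, seed = 1) {
  set.seed(seed)
  latent <- matrix(rnorm(2 * nSamples), 2, nSamples)
  genes <- c(sprintf("MA%02d", seq_len(nPerModule)),
             sprintf("MB%02d", seq_len(nPerModule)),
             if (nNoise) sprintf("NN%02d", seq_len(nNoise)))
  m <- matrix(rnorm(length(genes) * nSamples), length(genes), nSamples,
              dimnames = list(genes, sprintf("S%02d", seq_len(nSamples))))
  m[seq_len(nPerModule), ] <- m[seq_len(nPerModule), ] +
    signal * matrix(latent[1, ], nPerModule, nSamples, byrow = TRUE)
  m[nPerModule + seq_len(nPerModule), ] <-
    m[nPerModule + seq_len(nPerModule), ] +
    signal * matrix(latent[2, ], nPerModule, nSamples, byrow = TRUE)
  ExpressionMatrix(m)
}

test_that("Spearman distance matches a rank-then-Pearson oracle", {
  m <- exprValues(toyExpr(3, 4, seed = 2))
  d <- spearmanDistance(ExpressionMatrix(m))
  expect_equal(d, spearmanDistOracle(m), tolerance = 1e-12)
  # strictly monotone pair -> distance 0; anti-monotone -> 2
  mono <- ExpressionMatrix(matrix(c(1, 2, 3, 4, 1, 4, 9, 16, 4, 3, 2, 1),
                                  3, 4, byrow = TRUE,
                                  dimnames = list(c("up", "sq", "down"),
                                                  paste0("s", 1:4))))
  dm <- spearmanDistance(mono)
  expect_equal(dm["up", "sq"], 0, tolerance = 1e-12)
  expect_equal(dm["up", "down"], 2, tolerance = 1e-12)
  # a constant gene is an undefined rank correlation
  const <- ExpressionMatrix(matrix(c(1, 1, 1, 1, 1, 2, 3, 4), 2, 4,
                                   byrow = TRUE,
                                   dimnames = list(c("flat", "ok"),
                                                   paste0("s", 1:4))))
  expect_error(spearmanDistance(const), "flat")
})

test_that("no-resampling consensus is binary and equals the single run", {
  expr <- plantedModuleExpr(nPerModule = 6, nSamples = 20, seed = 3)
  prm <- consensusParams(reps = 5, p_item = 1, p_feature = 1, k = 2,
                         seed = 4)
  res <- consensusCluster(expr, params = prm)
  cm <- consensusMatrix(res)
  expect_true(all(cm %in% c(0, 1)))
  hc <- hclust(as.dist(spearmanDistance(expr)), method = "ward.D2")
  single <- cutree(hc, k = 2)
  asg <- clusterAssignments(res)[names(single)]
  expect_equal(length(unique(paste(asg, single))), 2L)
})

test_that("consensus recovers planted orthogonal modules", {
  skip_if_not_installed("mclust")
  expr <- plantedModuleExpr(nPerModule = 10, nSamples = 40, signal = 4,
                            seed = 5)
  res <- consensusCluster(expr, params = consensusParams(reps = 50,
                                                         p_item = 0.8,
                                                         k = 2, seed = 6))
  planted <- rep(1:2, each = 10)
  asg <- clusterAssignments(res)[geneIds(expr)]
  expect_equal(mclust::adjustedRandIndex(asg, planted), 1)
  cm <- consensusMatrix(res)
  within <- c(cm[1:10, 1:10][upper.tri(diag(10))],
              cm[11:20, 11:20][upper.tri(diag(10))])
  expect_true(all(within >= 0.9))
})

test_that("sampling counts equal an independent tally of the subsample stream", {
  expr <- plantedModuleExpr(nPerModule = 8, nNoise = 4, nSamples = 20,
                            seed = 7)
  prm <- consensusParams(reps = 40, p_item = 0.8, p_feature = 1, k = 3,
                         seed = 8)
  res <- consensusCluster(expr, params = prm)
  G <- length(geneIds(expr))
  nItem <- ceiling(prm$p_item * G)
  nFeat <- ceiling(prm$p_feature * length(sampleIds(expr)))
  tally <- matrix(0, G, G, dimnames = list(geneIds(expr), geneIds(expr)))
  set.seed(prm$seed)
  for (r in seq_len(prm$reps)) {
    gi <- sort(sample.int(G, nItem))
    si <- sort(sample.int(length(sampleIds(expr)), nFeat))
    tally[gi, gi] <- tally[gi, gi] + 1
  }
  expect_equal(samplingCounts(res), tally)
})

test_that("consensus is invariant to gene input order up to relabeling", {
  skip_if_not_installed("mclust")
  expr <- plantedModuleExpr(nPerModule = 6, nNoise = 3, nSamples = 25,
                            seed = 9)
  prm <- consensusParams(reps = 30, k = 3, seed = 10)
  res1 <- consensusCluster(expr, geneIds(expr), prm)
  perm <- rev(geneIds(expr))
  res2 <- consensusCluster(expr, perm, prm)
  a1 <- clusterAssignments(res1)[geneIds(expr)]
  a2 <- clusterAssignments(res2)[geneIds(expr)]
  expect_equal(mclust::adjustedRandIndex(a1, a2), 1)
})

test_that("Ward.D2 merge heights are non-decreasing on a consensus run", {
  expr <- plantedModuleExpr(nPerModule = 7, nNoise = 5, nSamples = 30,
                            seed = 11)
  res <- consensusCluster(expr, params = consensusParams(reps = 20, k = 3,
                                                         seed = 12))
  hc <- hclust(as.dist(1 - consensusMatrix(res)), method = "ward.D2")
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("selectCoexpressed returns the most coherent sufficiently large cluster", {
  expr <- plantedModuleExpr(nPerModule = 8, nNoise = 10, nSamples = 40,
                            signal = 4, seed = 13)
  res <- consensusCluster(expr, params = consensusParams(reps = 40, k = 4,
                                                         seed = 14))
  mod <- selectCoexpressed(res, expr, min_size = 5)
  expect_true(setName(mod) == "COEXPRESSED_MODULE")
  expect_true(all(grepl("^M[AB]", geneMembers(mod))))
  expect_error(selectCoexpressed(res, expr, min_size = 50), "min_size")
})
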