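rawParams <- scoreParams(normalize = FALSE)

test_that("ssGSEA raw scores equal the direct-summation oracle", {
  set.seed(1)
  for (i in 1:25) {
    nG <- sample(5:12, 1); nS <- sample(1:4, 1)
    expr <- toyExpr(nG, nS, seed = 100 + i)
    sig <- GeneSet("SIG", sample(geneIds(expr), sample(2:(nG - 1), 1)))
    got <- ssgseaScore(expr, sig, rawParams)
    for (s in sampleIds(expr)) {
      x <- setNames(exprValues(expr)[, s], geneIds(expr))
      expect_equal(got[[s]], ssgseaOracle(x, geneMembers(sig), 0.25),
                   tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA is rank-based: monotone transforms leave raw scores fixed", {
  expr <- toyExpr(20, 5, seed = 7)
  sig <- GeneSet("SIG", geneIds(expr)[c(2, 5, 9, 14)])
  base <- ssgseaScore(expr, sig, rawParams)
  shifted <- exprValues(expr)
  shifted[, 2] <- shifted[, 2] + 7            # constant shift, one sample
  shifted[, 4] <- exp(shifted[, 4])           # strictly monotone transform
  got <- ssgseaScore(ExpressionMatrix(shifted), sig, rawParams)
  expect_equal(got, base, tolerance = 1e-12)
})

test_that("signature genes at the top ranks maximize the one-sample score", {
  # 5 genes, 2-gene signature: enumerate all C(5,2) placements by permuting
  # which genes carry the two largest values
  vals <- c(5, 4, 3, 2, 1)
  combos <- combn(5, 2)
  scores <- apply(combos, 2, function(idx) {
    x <- matrix(vals, 5, 1,
                dimnames = list(paste0("g", 1:5), "s1"))
    sig <- GeneSet("SIG", paste0("g", idx))
    ssgseaScore(ExpressionMatrix(x), sig, rawParams)
  })
  expect_equal(which.max(scores),
               which(apply(combos, 2, function(i) all(i == c(1, 2)))))
})

test_that("ssGSEA rejects empty and all-covering signatures", {
  expr <- toyExpr(6, 2)
  expect_error(ssgseaScore(expr, GeneSet("NONE", "ZZZ"), rawParams),
               "no gene")
  expect_error(ssgseaScore(expr, GeneSet("ALL", geneIds(expr)), rawParams),
               "every gene")
})

test_that("global normalization divides by the score range", {
  expr <- toyExpr(15, 6, seed = 3)
  sig <- GeneSet("SIG", geneIds(expr)[1:4])
  raw <- ssgseaScore(expr, sig, rawParams)
  norm <- ssgseaScore(expr, sig, scoreParams(normalize = TRUE))
  expect_equal(norm, raw / (max(raw) - min(raw)), tolerance = 1e-12)
})

test_that("weighted signature score is the weighted sum of z-scores", {
  m <- matrix(c(1, 2, 3,
                4, 6, 8,
                0, 5, 10), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  expr <- ExpressionMatrix(m)
  sig <- WeightedGeneSet("W", c("A", "B", "C"), c(0.5, -1, 2))
  z <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  expected <- colSums(z * c(0.5, -1, 2))
  expect_equal(weightedSignatureScore(expr, sig), expected,
               tolerance = 1e-12)
  # zero weights give zero scores; single gene weight 1 returns its z-score
  zero <- WeightedGeneSet("Z", c("A", "B"), c(0, 0))
  expect_equal(unname(weightedSignatureScore(expr, zero)), rep(0, 3))
  one <- WeightedGeneSet("O", "B", 1)
  expect_equal(weightedSignatureScore(expr, one), z["B", ],
               tolerance = 1e-12)
  # structural errors
  expect_error(weightedSignatureScore(expr, WeightedGeneSet("M", "D", 1)),
               "missing.*D")
  flat <- ExpressionMatrix(rbind(m, FLAT = c(1, 1, 1)))
  expect_error(
    weightedSignatureScore(flat, WeightedGeneSet("F", "FLAT", 1)),
    "zero variance")
})

test_that("ESTIMATE scores decompose and apply the published purity formula", {
  expr <- toyExpr(40, 5, seed = 5)
  stro <- GeneSet("STROMAL", geneIds(expr)[1:8])
  immu <- GeneSet("IMMUNE", geneIds(expr)[9:16])
  est <- estimateScores(expr, stro, immu)
  expect_equal(est$estimate_score, est$stromal_score + est$immune_score,
               tolerance = 1e-12)
  expect_equal(est$tumor_purity,
               cos(0.6049872018 + 0.0001467884 * est$estimate_score),
               tolerance = 1e-12)
  expect_equal(estimatePurity(0), cos(0.6049872018), tolerance = 1e-12)
  expect_equal(estimatePurity(0), 0.8223, tolerance = 1e-3)
  # identical samples give identical scores
  m <- exprValues(expr); m[, 2] <- m[, 1]
  est2 <- estimateScores(ExpressionMatrix(m), stro, immu)
  expect_equal(est2$tumor_purity[1], est2$tumor_purity[2])
})

test_that("ORA p-values match exhaustive hypergeometric summation", {
  universe <- paste0("u", 1:12)
  set.seed(2)
  for (i in 1:15) {
    K <- sample(5:9, 1); n <- sample(3:8, 1)
    term <- GeneSet("T", sample(universe, K))
    query <- GeneSet("Q", sample(universe, n))
    res <- oraEnrichment(query, SignatureCollection(list(term)), universe,
                         min_set = 1)
    k <- length(intersect(geneMembers(term), geneMembers(query)))
    expect_equal(res$p, oraOracle(k, K, n, 12), tolerance = 1e-12)
  }
})

test_that("ORA honors the published filters and exact corner cases", {
  universe <- paste0("g", 1:20)
  hit <- GeneSet("HIT", universe[1:5])
  small <- GeneSet("SMALL", universe[6:9])     # size 4 < min_set
  disjoint <- GeneSet("FAR", universe[11:16])
  res <- oraEnrichment(GeneSet("Q", universe[1:5]),
                       SignatureCollection(list(hit, small, disjoint)),
                       universe, min_set = 5, max_set = 5000)
  expect_false("SMALL" %in% res$term)
  # perfect overlap: p = 1 / choose(20, 5)
  expect_equal(res$p[res$term == "HIT"], 1 / 15504, tolerance = 1e-12)
  expect_true(res$significant[res$term == "HIT"])
  # disjoint term: k = 0, p = 1
  expect_equal(res$overlap[res$term == "FAR"], 0L)
  expect_equal(res$p[res$term == "FAR"], 1)
  # BH is monotone: p-order equals q-order
  expect_equal(order(res$p), order(res$q))
  expect_true(all(res$q >= res$p))
  expect_error(oraEnrichment(GeneSet("Q", "nope"),
                             SignatureCollection(list(hit)), universe),
               "outside universe")
})
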