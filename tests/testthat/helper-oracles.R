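# Shared fixtures and independent oracles, kept deliberately naive
# (loops, explicit sums) so they stay independent of the package's
# vectorized implementations.

toyExpr <- function(nGenes, nSamples, seed = 1) {
  set.seed(seed)
  ExpressionMatrix(matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                          dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                                          sprintf("S%02d", seq_len(nSamples)))))
}

# direct-summation ssGSEA oracle: walk the decreasing-expression order,
# accumulating in-set weighted and out-of-set uniform CDFs step by step
ssgseaOracle <- function(x, sigGenes, alpha) {
  N <- length(x)
  inSet <- names(x) %in% sigGenes
  r <- rank(x, ties.method = "average")
  walk <- order(-x)
  wTotal <- 0
  for (i in which(inSet)) wTotal <- wTotal + r[i]^alpha
  pin <- 0; pout <- 0; es <- 0
  for (i in walk) {
    if (inSet[i]) pin <- pin + r[i]^alpha / wTotal
    else pout <- pout + 1 / (N - sum(inSet))
    es <- es + (pin - pout)
  }
  unname(es)
}

# Spearman distance oracle: rank each gene, then Pearson of the ranks from
# the covariance definition
spearmanDistOracle <- function(m) {
  G <- nrow(m)
  ranks <- t(apply(m, 1, rank))
  d <- matrix(0, G, G, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(G)) for (j in seq_len(G)) {
    a <- ranks[i, ]; b <- ranks[j, ]
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    d[i, j] <- 1 - num / den
  }
  diag(d) <- 0
  d
}

# observed/expected/variance log-rank sums for two groups, summed over
# distinct event times
logrankOracle2 <- function(time, event, group) {
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2)
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == lev[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# hypergeometric upper tail by direct summation over the overlap count
oraOracle <- function(k, K, n, N) {
  p <- 0
  for (j in k:min(K, n))
    p <- p + choose(K, j) * choose(N - K, n - j) / choose(N, n)
  p
}

# inverse-variance pooling by explicit formulas
poolOracle <- function(d, se, method = "fixed") {
  w <- 1 / se^2
  mu <- sum(w * d) / sum(w)
  Q <- sum(w * (d - mu)^2)
  df <- length(d) - 1
  if (method == "fixed") return(list(mu = mu, se = sqrt(1 / sum(w)), Q = Q))
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(mu = sum(ws * d) / sum(ws), se = sqrt(1 / sum(ws)), Q = Q,
       tau2 = tau2)
}

# closed-form simple OLS for the Egger regression
eggerOracle <- function(d, se) {
  y <- d / se; x <- 1 / se
  n <- length(d)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  s2 <- sum(resid^2) / (n - 2)
  seA <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  list(intercept = a, se = seA, t = a / seA,
       p = 2 * pt(-abs(a / seA), n - 2))
}

# full stratification recovery on a generated cohort: returns subtype and
# phenotype accuracy against the planted truth
recoveryAccuracy <- function(cohort) {
  tc <- weightedSignatureScore(cohort$expression, tcellInflamedSignature())
  calls <- callStrata(
    cohort$expression,
    GeneSet("GLY", grep("^GLY", geneIds(cohort$expression), value = TRUE)),
    GeneSet("CHO", grep("^CHO", geneIds(cohort$expression), value = TRUE)),
    tc, cohort$clinical)
  truth <- cohort$truth
  c(subtype = mean(calls$metabolic_subtype == truth$subtype),
    phenotype = mean(calls$immune_phenotype == truth$phenotype))
}
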