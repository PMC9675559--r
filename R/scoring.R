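#' ssGSEA scoring parameters
#'
#' @param alpha rank-weight exponent (>= 0, default 0.25, the conventional
#'   ssGSEA setting).
#' @param normalize divide all scores by the global (max - min) of the raw
#'   score matrix (default TRUE, the conventional ssGSEA setting).
#' @return validated list of class \code{scoreParams}.
#' @export
scoreParams <- function(alpha = 0.25, normalize = TRUE) {
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(alpha = alpha, normalize = isTRUE(normalize)),
            class = "scoreParams")
}

# raw single-sample enrichment score for one sample's expression vector
ssgseaSampleScore <- function(x, inSet, alpha) {
  N <- length(x)
  r <- rank(x, ties.method = "average")        # high expression -> high rank
  ord <- order(x, decreasing = TRUE)
  inOrd <- inSet[ord]
  w <- r[ord]^alpha
  w[!inOrd] <- 0
  stepIn <- cumsum(w) / sum(w)
  stepOut <- cumsum(!inOrd) / (N - sum(inSet))
  sum(stepIn - stepOut)
}

#' Single-sample GSEA enrichment score
#'
#' Per sample, genes are ranked by decreasing expression (average ranks for
#' ties); the enrichment score is the sum over rank positions of the
#' difference between the in-set cumulative weight (weights equal the rank
#' statistic raised to \code{alpha}, normalized to sum 1 over set members)
#' and the out-of-set cumulative fraction. With \code{normalize = TRUE}
#' every score is divided by the (max - min) of the raw scores.
#'
#' The raw score depends on expression only through within-sample ranks, so
#' it is invariant under any strictly monotone transform of one sample's
#' expression vector.
#'
#' @param expr an \code{\linkS4class{ExpressionMatrix}}.
#' @param sig a \code{\linkS4class{GeneSet}}; at least one member must be in
#'   the matrix and the membership must not cover every gene.
#' @param params a \code{\link{scoreParams}}.
#' @return named numeric vector, sample_id -> score.
#' @export
ssgseaScore <- function(expr, sig, params = scoreParams()) {
  stopifnot(is(expr, "ExpressionMatrix"), inherits(params, "scoreParams"))
  m <- exprValues(expr)
  inSet <- rownames(m) %in% geneMembers(sig)
  if (!any(inSet))
    stop(sprintf("no gene of signature '%s' present in the matrix",
                 setName(sig)))
  if (all(inSet))
    stop("signature covers every gene; out-of-set step is undefined")
  raw <- apply(m, 2L, ssgseaSampleScore, inSet = inSet,
               alpha = params$alpha)
  if (params$normalize) {
    rng <- max(raw) - min(raw)
    if (rng == 0) {
      warning("raw score range is zero; normalization skipped")
    } else raw <- raw / rng
  }
  raw
}

#' Score a collection of signatures by ssGSEA
#'
#' Computes the raw ssGSEA score for every signature and, when
#' \code{params$normalize}, divides the whole signatures x samples matrix by
#' its global (max - min), matching the conventional joint normalization.
#' Signatures without any gene in the matrix are dropped with a warning.
#'
#' @param expr an ExpressionMatrix.
#' @param collection a \code{\linkS4class{SignatureCollection}}.
#' @param params a \code{\link{scoreParams}}.
#' @return signatures x samples numeric matrix.
#' @export
scoreSignatures <- function(expr, collection, params = scoreParams()) {
  stopifnot(is(collection, "SignatureCollection"))
  rawParams <- scoreParams(alpha = params$alpha, normalize = FALSE)
  present <- vapply(geneSets(collection), function(s)
    any(geneMembers(s) %in% geneIds(expr)), logical(1))
  if (!any(present)) stop("no signature overlaps the matrix")
  if (any(!present))
    warning(sprintf("signature(s) without any gene in the matrix dropped: %s",
                    paste(signatureNames(collection)[!present],
                          collapse = ", ")))
  sets <- geneSets(collection)[present]
  scores <- t(vapply(sets, function(s) ssgseaScore(expr, s, rawParams),
                     numeric(length(sampleIds(expr)))))
  colnames(scores) <- sampleIds(expr)
  if (params$normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) warning("raw score range is zero; normalization skipped")
    else scores <- scores / rng
  }
  scores
}

#' Weighted-signature score (weighted sum of z-scored expression)
#'
#' score(sample) = sum over signature genes of weight * z, where z is the
#' gene's cohort z-scored expression. Used for the 18-gene T-cell-inflamed
#' score.
#'
#' @param expr an ExpressionMatrix containing every signature gene (missing
#'   genes are an error listing them).
#' @param sig a \code{\linkS4class{WeightedGeneSet}}; a member gene with zero
#'   variance across the cohort is an error naming it.
#' @return named numeric vector, sample_id -> score.
#' @export
weightedSignatureScore <- function(expr, sig) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sig, "WeightedGeneSet"))
  genes <- geneMembers(sig)
  missing <- setdiff(genes, geneIds(expr))
  if (length(missing))
    stop(sprintf("signature gene(s) missing from matrix: %s",
                 paste(missing, collapse = ", ")))
  m <- exprValues(expr)[genes, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  if (any(s == 0))
    stop(sprintf("signature gene with zero variance: %s",
                 genes[s == 0][1L]))
  z <- (m - mu) / s
  colSums(z * geneWeights(sig))
}

#' ESTIMATE stromal / immune / purity scores
#'
#' Stromal and immune scores are raw ssGSEA scores (no global normalization)
#' of the two signatures; the ESTIMATE score is their sum; tumor purity
#' applies the published calibration
#' purity = cos(0.6049872018 + 0.0001467884 * estimate_score).
#' Purity values falling outside [0, 1] are flagged, never clipped.
#'
#' @param expr an ExpressionMatrix.
#' @param stromal_sig,immune_sig \code{\linkS4class{GeneSet}}s; defaults are
#'   the packaged synthetic stand-ins.
#' @param alpha ssGSEA rank-weight exponent.
#' @return data.frame per sample: \code{sample_id}, \code{stromal_score},
#'   \code{immune_score}, \code{estimate_score}, \code{tumor_purity},
#'   \code{purity_in_range}.
#' @export
estimateScores <- function(expr,
                           stromal_sig = estimateSignatures()[["STROMAL_SIGNATURE"]],
                           immune_sig = estimateSignatures()[["IMMUNE_SIGNATURE"]],
                           alpha = 0.25) {
  p <- scoreParams(alpha = alpha, normalize = FALSE)
  stromal <- ssgseaScore(expr, stromal_sig, p)
  immune <- ssgseaScore(expr, immune_sig, p)
  est <- stromal + immune
  purity <- estimatePurity(est)
  data.frame(sample_id = sampleIds(expr), stromal_score = stromal,
             immune_score = immune, estimate_score = est,
             tumor_purity = purity,
             purity_in_range = purity >= 0 & purity <= 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published ESTIMATE purity calibration
#'
#' @param estimate_score numeric ESTIMATE score(s).
#' @return cos(0.6049872018 + 0.0001467884 * estimate_score).
#' @export
estimatePurity <- function(estimate_score) {
  cos(0.6049872018 + 0.0001467884 * estimate_score)
}

#' Hypergeometric over-representation analysis
#'
#' For every term set (intersected with the universe, then filtered to sizes
#' in [\code{min_set}, \code{max_set}]), computes the hypergeometric
#' upper-tail probability P(X >= k) of observing at least the realized
#' overlap k between the query and the term, with BH adjustment across the
#' retained terms. Rows are sorted by p.
#'
#' @param query a \code{\linkS4class{GeneSet}}; must be a subset of the
#'   universe.
#' @param collections a \code{\linkS4class{SignatureCollection}} of terms.
#' @param universe character vector of background genes.
#' @param min_set,max_set retained term-size bounds after intersection with
#'   the universe (defaults 5 and 5000).
#' @param alpha significance level applied to the raw p (default 0.05).
#' @return data.frame with \code{term}, \code{overlap} (k), \code{term_size}
#'   (K), \code{query_size} (n), \code{universe_size} (N), \code{p},
#'   \code{q}, \code{significant}.
#' @export
oraEnrichment <- function(query, collections, universe,
                          min_set = 5L, max_set = 5000L, alpha = 0.05) {
  stopifnot(is(query, "GeneSet"), is(collections, "SignatureCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  qGenes <- geneMembers(query)
  if (!length(qGenes)) stop("empty query")
  outside <- setdiff(qGenes, universe)
  if (length(outside))
    stop(sprintf("query gene(s) outside universe: %s",
                 paste(outside, collapse = ", ")))
  N <- length(universe)
  n <- length(qGenes)
  rows <- lapply(geneSets(collections), function(s) {
    term <- intersect(geneMembers(s), universe)
    K <- length(term)
    if (K < min_set || K > max_set) return(NULL)
    k <- length(intersect(qGenes, term))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = setName(s), overlap = k, term_size = K,
               query_size = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no term passes the size filter")
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
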