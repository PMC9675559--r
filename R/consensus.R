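#' Parameters for resampled consensus clustering
#'
#' Defaults follow the module-discovery setup the pipeline reproduces:
#' 100 repetitions, 80\% of genes (items) resampled per repetition, all
#' samples retained, k = 5 clusters, Ward.D2 linkage on one-minus-Spearman
#' distance.
#'
#' @param reps number of resampling repetitions (>= 1).
#' @param p_item fraction of genes subsampled per repetition, in (0, 1].
#' @param p_feature fraction of samples subsampled per repetition, in (0, 1].
#' @param k number of clusters (>= 2).
#' @param linkage agglomeration method; only \code{"ward.D2"} is supported.
#' @param seed integer RNG seed for the subsample stream.
#' @return validated list of class \code{consensusParams}.
#' @export
consensusParams <- function(reps = 100L, p_item = 0.8, p_feature = 1,
                            k = 5L, linkage = "ward.D2", seed = 1L) {
  if (reps < 1) stop("reps must be >= 1")
  if (p_item <= 0 || p_item > 1) stop("p_item must lie in (0, 1]")
  if (p_feature <= 0 || p_feature > 1) stop("p_feature must lie in (0, 1]")
  if (k < 2) stop("k must be >= 2")
  linkage <- match.arg(linkage, "ward.D2")
  structure(list(reps = as.integer(reps), p_item = p_item,
                 p_feature = p_feature, k = as.integer(k), linkage = linkage,
                 seed = as.integer(seed)),
            class = "consensusParams")
}

#' One-minus-Spearman correlation distance between genes
#'
#' d(i, j) = 1 - rho_s(i, j), where rho_s is the Spearman rank correlation of
#' the two genes' expression across samples. Symmetric, zero diagonal,
#' range [0, 2].
#'
#' @param expr an \code{\linkS4class{ExpressionMatrix}}.
#' @param genes subset of \code{geneIds(expr)} (default: all); >= 2 genes and
#'   >= 3 samples required. A gene constant across the samples (undefined
#'   rank correlation) is an error naming the gene.
#' @return a symmetric numeric matrix over \code{genes}.
#' @export
spearmanDistance <- function(expr, genes = geneIds(expr)) {
  stopifnot(is(expr, "ExpressionMatrix"))
  missing <- setdiff(genes, geneIds(expr))
  if (length(missing))
    stop(sprintf("genes not in matrix: %s", paste(missing, collapse = ", ")))
  m <- exprValues(expr)[genes, , drop = FALSE]
  if (nrow(m) < 2L) stop("need >= 2 genes")
  if (ncol(m) < 3L) stop("need >= 3 samples")
  const <- apply(m, 1L, function(r) max(r) == min(r))
  if (any(const))
    stop(sprintf("gene constant across samples: %s",
                 rownames(m)[const][1L]))
  d <- 1 - cor(t(m), method = "spearman")
  d[abs(d) < .Machine$double.eps * 4] <- 0
  diag(d) <- 0
  d
}

#' Resampled consensus hierarchical clustering of genes
#'
#' For each repetition, subsample \code{ceiling(p_item * |genes|)} genes and
#' \code{ceiling(p_feature * n_samples)} samples without replacement, cluster
#' the gene subsample hierarchically (Ward.D2 on one-minus-Spearman distance
#' computed over the sample subsample) and cut at k. The consensus index of a
#' gene pair is its co-clustering count divided by its co-sampling count; a
#' pair never co-sampled gets consensus 0 with a warning. Final assignments
#' come from Ward.D2 hierarchical clustering of (1 - consensus), cut at k.
#' Deterministic under \code{params$seed}.
#'
#' @param expr an ExpressionMatrix.
#' @param genes subset of gene ids to cluster (default: all); at least k.
#' @param params a \code{\link{consensusParams}}.
#' @return a \code{\linkS4class{ConsensusResult}}.
#' @export
consensusCluster <- function(expr, genes = geneIds(expr),
                             params = consensusParams()) {
  stopifnot(is(expr, "ExpressionMatrix"), inherits(params, "consensusParams"))
  genes <- as.character(genes)
  G <- length(genes)
  if (G < params$k) stop("fewer genes than clusters requested")
  nSamp <- length(sampleIds(expr))
  nItem <- ceiling(params$p_item * G)
  nFeat <- ceiling(params$p_feature * nSamp)
  if (nItem < params$k)
    stop("p_item subsample smaller than k; increase p_item or reduce k")
  m <- exprValues(expr)[genes, , drop = FALSE]

  cocluster <- matrix(0, G, G, dimnames = list(genes, genes))
  cosample <- matrix(0, G, G, dimnames = list(genes, genes))
  withSeed(params$seed, {
    for (r in seq_len(params$reps)) {
      gi <- sort(sample.int(G, nItem))
      si <- sort(sample.int(nSamp, nFeat))
      sub <- m[gi, si, drop = FALSE]
      d <- 1 - cor(t(sub), method = "spearman")
      if (any(!is.finite(d)))
        stop("a gene is constant within a subsample; Spearman undefined")
      hc <- hclust(as.dist(d), method = params$linkage)
      cl <- cutree(hc, k = params$k)
      cosample[gi, gi] <- cosample[gi, gi] + 1
      for (lab in unique(cl)) {
        members <- gi[cl == lab]
        cocluster[members, members] <- cocluster[members, members] + 1
      }
    }
  })
  consensus <- matrix(0, G, G, dimnames = list(genes, genes))
  seen <- cosample > 0
  consensus[seen] <- cocluster[seen] / cosample[seen]
  if (any(!seen[upper.tri(seen)]))
    warning("some gene pairs were never co-sampled; their consensus is 0")
  diag(consensus) <- 1

  hcFinal <- hclust(as.dist(1 - consensus), method = params$linkage)
  assignments <- cutree(hcFinal, k = params$k)
  new("ConsensusResult", consensus = consensus,
      assignments = as.integer(assignments) |>
        setNames(names(assignments)),
      samplingCounts = cosample, k = params$k)
}

# mean pairwise Spearman correlation among a set of genes
meanIntraSpearman <- function(expr, genes) {
  if (length(genes) < 2L) return(NA_real_)
  rho <- cor(t(exprValues(expr)[genes, , drop = FALSE]), method = "spearman")
  mean(rho[upper.tri(rho)])
}

#' Select the most coherent coexpressed gene cluster
#'
#' Among clusters of size >= \code{min_size}, returns the one with the
#' highest mean pairwise Spearman correlation of its member genes (computed
#' on the full expression matrix); exact ties break toward the smaller
#' cluster label.
#'
#' @param result a \code{\linkS4class{ConsensusResult}}.
#' @param expr the ExpressionMatrix the result was computed from.
#' @param min_size minimum cluster size considered (default 5).
#' @param name name given to the returned gene set.
#' @return a \code{\linkS4class{GeneSet}} of the selected cluster's genes.
#' @export
selectCoexpressed <- function(result, expr, min_size = 5L,
                              name = "COEXPRESSED_MODULE") {
  stopifnot(is(result, "ConsensusResult"), is(expr, "ExpressionMatrix"))
  asg <- clusterAssignments(result)
  missing <- setdiff(names(asg), geneIds(expr))
  if (length(missing))
    stop(sprintf("clustered genes absent from matrix: %s",
                 paste(missing, collapse = ", ")))
  sizes <- table(asg)
  eligible <- as.integer(names(sizes)[sizes >= min_size])
  if (!length(eligible))
    stop(sprintf("no cluster reaches min_size = %d", min_size))
  coherence <- vapply(eligible, function(lab)
    meanIntraSpearman(expr, names(asg)[asg == lab]), numeric(1))
  best <- eligible[order(-coherence, eligible)][1L]
  GeneSet(name, names(asg)[asg == best])
}
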