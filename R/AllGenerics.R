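#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @export
setGeneric("geneMembers", function(x) standardGeneric("geneMembers"))
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))
#' @export
setGeneric("samplingCounts", function(x) standardGeneric("samplingCounts"))
#' @export
setGeneric("pooledLogHR", function(x) standardGeneric("pooledLogHR"))
#' @export
setGeneric("pooledSE", function(x) standardGeneric("pooledSE"))
#' @export
setGeneric("pooledHR", function(x) standardGeneric("pooledHR"))
#' @export
setGeneric("confint95", function(x) standardGeneric("confint95"))
#' @export
setGeneric("heterogeneity", function(x) standardGeneric("heterogeneity"))

#' Accessors for the MetaboStrat S4 containers
#'
#' \code{geneIds}/\code{sampleIds}/\code{exprValues} access an
#' \code{ExpressionMatrix}; \code{setName}/\code{geneMembers}/
#' \code{geneWeights} access gene sets; \code{signatureNames}/\code{geneSets}
#' access a \code{SignatureCollection}; \code{consensusMatrix}/
#' \code{clusterAssignments}/\code{samplingCounts} a \code{ConsensusResult};
#' \code{pooledLogHR}/\code{pooledSE}/\code{pooledHR}/\code{confint95}/
#' \code{heterogeneity} a \code{MetaResult}.
#'
#' @param x the object.
#' @return the slot content (see each accessor); \code{confint95} returns the
#'   95\% CI of the pooled hazard ratio on the HR scale; \code{heterogeneity}
#'   a named vector with \code{Q}, \code{df}, \code{i2}, \code{tau2}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(object@values), ncol(object@values)))
  cat("genes:  ", paste(head(rownames(object@values), 4), collapse = ", "),
      if (nrow(object@values) > 4) ", ..." else "", "\n", sep = "")
  cat("samples:", paste(head(colnames(object@values), 4), collapse = ", "),
      if (ncol(object@values) > 4) ", ..." else "", "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("setName", "GeneSet", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("setName", "WeightedGeneSet", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("geneMembers", "GeneSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("geneMembers", "WeightedGeneSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("geneWeights", "WeightedGeneSet",
          function(x) setNames(x@weights, x@genes))

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d genes)\n", object@name, length(object@genes)))
})
setMethod("show", "WeightedGeneSet", function(object) {
  cat(sprintf("WeightedGeneSet '%s' (%d genes, weights in [%.3g, %.3g])\n",
              object@name, length(object@genes), min(object@weights),
              max(object@weights)))
})

#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureCollection",
          function(x) names(x@sets))
#' @rdname accessors
#' @export
setMethod("geneSets", "SignatureCollection", function(x) x@sets)

setMethod("length", "SignatureCollection", function(x) length(x@sets))

setMethod("[[", "SignatureCollection", function(x, i) x@sets[[i]])

setMethod("show", "SignatureCollection", function(object) {
  cat(sprintf("SignatureCollection of %d sets\n", length(object@sets)))
  if (length(object@sets))
    cat("  ", paste(head(names(object@sets), 6), collapse = ", "),
        if (length(object@sets) > 6) ", ..." else "", "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "ConsensusResult", function(x) x@assignments)
#' @rdname accessors
#' @export
setMethod("samplingCounts", "ConsensusResult", function(x) x@samplingCounts)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d items, k = %d\n",
              nrow(object@consensus), object@k))
  print(table(cluster = object@assignments))
})

#' @rdname accessors
#' @export
setMethod("pooledLogHR", "MetaResult", function(x) x@pooledLogHR)
#' @rdname accessors
#' @export
setMethod("pooledSE", "MetaResult", function(x) x@pooledSE)
#' @rdname accessors
#' @export
setMethod("pooledHR", "MetaResult", function(x) exp(x@pooledLogHR))
#' @rdname accessors
#' @export
setMethod("confint95", "MetaResult", function(x) {
  z <- 1.959964
  setNames(exp(x@pooledLogHR + c(-1, 1) * z * x@pooledSE),
           c("lower", "upper"))
})
#' @rdname accessors
#' @export
setMethod("heterogeneity", "MetaResult", function(x) {
  c(Q = x@Q, df = x@df, i2 = x@i2, tau2 = x@tau2)
})

setMethod("show", "MetaResult", function(object) {
  ci <- confint95(object)
  cat(sprintf("MetaResult (%s, k = %d)\n", object@method, object@k))
  cat(sprintf("  pooled HR %.3f [%.3f, %.3f]\n",
              exp(object@pooledLogHR), ci[1], ci[2]))
  cat(sprintf("  Q = %.3f (df = %d), I2 = %.1f%%, tau2 = %.4f\n",
              object@Q, as.integer(object@df), object@i2, object@tau2))
})
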