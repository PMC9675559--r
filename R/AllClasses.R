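#' @import methods
#' @importFrom stats cor cutree hclust as.dist median sd rexp runif
#'   rnorm rbinom setNames pchisq phyper p.adjust t.test wilcox.test aov
#'   TukeyHSD kruskal.test chisq.test pt pnorm lm
#' @importFrom utils read.delim write.table head combn
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' ExpressionMatrix: genes x samples log-scale expression
#'
#' Thin S4 container for a log-scale normalized expression matrix with unique
#' gene and sample identifiers and no missing or non-finite entries.
#'
#' @slot values numeric matrix, rows = genes, cols = samples; dimnames carry
#'   the gene and sample identifiers.
#'
#' @examples
#' m <- ExpressionMatrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
#' geneIds(m)
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

validExpressionMatrix <- function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicate gene id: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicate sample id: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (is.numeric(v) && !all(is.finite(v)))
    msg <- c(msg, "values contain missing or non-finite entries")
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionMatrix", validExpressionMatrix)

#' @param values numeric genes x samples matrix with dimnames
#' @rdname ExpressionMatrix-class
#' @export
ExpressionMatrix <- function(values) {
  new("ExpressionMatrix", values = as.matrix(values))
}

#' GeneSet: a named collection of gene symbols
#'
#' @slot name single string naming the set.
#' @slot genes character vector of unique gene symbols, non-empty.
#' @export
setClass("GeneSet", representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@genes) == 0L) msg <- c(msg, "gene set is empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, sprintf("duplicate gene in set: %s",
                          object@genes[duplicated(object@genes)][1L]))
  if (length(msg)) msg else TRUE
})

#' @param name set name
#' @param genes character vector of gene symbols
#' @rdname GeneSet-class
#' @export
GeneSet <- function(name, genes) {
  new("GeneSet", name = as.character(name), genes = as.character(genes))
}

#' WeightedGeneSet: an ordered gene list with per-gene weights
#'
#' Houses weighted signatures such as the 18-gene T-cell-inflamed score:
#' score(sample) = sum over genes of weight * z-scored expression.
#'
#' @slot name single string.
#' @slot genes ordered character vector, no duplicates.
#' @slot weights numeric vector, one weight per gene.
#' @export
setClass("WeightedGeneSet",
         representation(name = "character", genes = "character",
                        weights = "numeric"))

setValidity("WeightedGeneSet", function(object) {
  msg <- character()
  if (length(object@genes) != length(object@weights))
    msg <- c(msg, "genes and weights differ in length")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene in weighted set")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' @param name set name
#' @param genes gene symbols
#' @param weights numeric weights aligned with \code{genes}
#' @rdname WeightedGeneSet-class
#' @export
WeightedGeneSet <- function(name, genes, weights) {
  new("WeightedGeneSet", name = as.character(name),
      genes = as.character(genes), weights = as.numeric(weights))
}

#' SignatureCollection: named list of GeneSet / WeightedGeneSet
#'
#' @slot sets list of GeneSet or WeightedGeneSet objects; element names equal
#'   the set names and are unique.
#' @export
setClass("SignatureCollection", representation(sets = "list"))

setValidity("SignatureCollection", function(object) {
  msg <- character()
  ok <- vapply(object@sets, function(s)
    is(s, "GeneSet") || is(s, "WeightedGeneSet"), logical(1))
  if (!all(ok)) msg <- c(msg, "all elements must be GeneSet/WeightedGeneSet")
  nms <- vapply(object@sets, function(s) s@name, character(1))
  if (!identical(unname(nms), names(object@sets)))
    msg <- c(msg, "element names must match set names")
  if (anyDuplicated(nms))
    msg <- c(msg, sprintf("duplicate set name: %s", nms[duplicated(nms)][1L]))
  if (length(msg)) msg else TRUE
})

#' @param sets list of GeneSet / WeightedGeneSet
#' @rdname SignatureCollection-class
#' @export
SignatureCollection <- function(sets = list()) {
  names(sets) <- vapply(sets, function(s) s@name, character(1))
  new("SignatureCollection", sets = sets)
}

#' ConsensusResult: resampled co-clustering summary over genes
#'
#' @slot consensus symmetric matrix in [0,1], unit diagonal; co-clustering
#'   frequency among co-sampled repetitions.
#' @slot assignments named integer vector, gene -> cluster label in 1..k.
#' @slot samplingCounts symmetric integer matrix; times each pair was
#'   co-sampled across repetitions.
#' @slot k number of clusters requested.
#' @export
setClass("ConsensusResult",
         representation(consensus = "matrix", assignments = "integer",
                        samplingCounts = "matrix", k = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  cm <- object@consensus
  if (!isSymmetric(unname(cm), tol = 1e-12)) msg <- c(msg, "consensus not symmetric")
  if (any(cm < -1e-12 | cm > 1 + 1e-12)) msg <- c(msg, "consensus outside [0,1]")
  if (any(abs(diag(cm) - 1) > 1e-12)) msg <- c(msg, "consensus diagonal != 1")
  if (!identical(sort(unique(names(object@assignments))), sort(rownames(cm))))
    msg <- c(msg, "assignments must cover all clustered items")
  if (length(msg)) msg else TRUE
})

#' MetaResult: pooled hazard-ratio meta-analysis summary
#'
#' @slot method "fixed" or "random-DL".
#' @slot pooledLogHR pooled log hazard ratio.
#' @slot pooledSE standard error of the pooled log HR.
#' @slot Q Cochran's heterogeneity statistic (fixed-effect weights).
#' @slot df degrees of freedom, k - 1.
#' @slot i2 I-squared in percent, max(0, (Q - df)/Q) * 100.
#' @slot tau2 DerSimonian-Laird between-study variance (0 for fixed).
#' @slot k number of studies pooled.
#' @export
setClass("MetaResult",
         representation(method = "character", pooledLogHR = "numeric",
                        pooledSE = "numeric", Q = "numeric", df = "numeric",
                        i2 = "numeric", tau2 = "numeric", k = "integer"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (!object@method %in% c("fixed", "random-DL"))
    msg <- c(msg, "method must be 'fixed' or 'random-DL'")
  if (object@method == "fixed" && object@tau2 != 0)
    msg <- c(msg, "fixed-effect result must have tau2 = 0")
  if (object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
  if (object@i2 < 0 || object@i2 > 100) msg <- c(msg, "i2 outside [0,100]")
  if (length(msg)) msg else TRUE
})
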