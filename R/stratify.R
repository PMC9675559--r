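#' Gene-wise z-scoring of an expression matrix
#'
#' Centers every gene to mean 0 and SD 1 across samples, so that a value of
#' 0 means cohort-average expression — the anchoring the quadrant subtype
#' rule relies on. Genes with zero variance are dropped with a warning.
#'
#' @param expr an \code{\linkS4class{ExpressionMatrix}}.
#' @return a centered ExpressionMatrix (possibly with fewer genes).
#' @export
zscoreGenes <- function(expr) {
  stopifnot(is(expr, "ExpressionMatrix"))
  m <- exprValues(expr)
  s <- apply(m, 1L, sd)
  if (all(s == 0)) stop("all genes are constant; nothing to z-score")
  if (any(s == 0)) {
    warning(sprintf("dropping constant gene(s): %s",
                    paste(rownames(m)[s == 0], collapse = ", ")))
    m <- m[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  ExpressionMatrix((m - rowMeans(m)) / s)
}

#' Per-sample median expression of a gene signature
#'
#' The per-sample median of the (typically z-scored) expression over the
#' signature genes present in the matrix; an even member count takes the
#' mean of the two central values.
#'
#' @param centered an ExpressionMatrix (gene-wise centered for the quadrant
#'   rule to be meaningful).
#' @param sig a \code{\linkS4class{GeneSet}}; at least one member must be
#'   present.
#' @return named numeric vector, sample_id -> median score.
#' @export
pathwayMedianScore <- function(centered, sig) {
  stopifnot(is(centered, "ExpressionMatrix"), is(sig, "GeneSet"))
  genes <- intersect(geneMembers(sig), geneIds(centered))
  if (!length(genes))
    stop(sprintf("no gene of signature '%s' present in the matrix",
                 setName(sig)))
  apply(exprValues(centered)[genes, , drop = FALSE], 2L, median)
}

#' Quadrant rule for metabolic subtype assignment
#'
#' quiescent: gly <= 0 and chol <= 0; glycolytic: gly > 0 and gly > chol;
#' cholesterol: chol > 0 and chol > gly. An exact positive tie
#' (gly = chol > 0) is not covered by the rule and returns
#' \code{"unclassified"} with a warning.
#'
#' @param gly,chol finite numeric vectors of per-sample glycolytic and
#'   cholesterol module scores (recycled to common length).
#' @return character vector of subtypes.
#' @export
assignMetabolicSubtype <- function(gly, chol) {
  if (any(!is.finite(gly)) || any(!is.finite(chol)))
    stop("module scores must be finite")
  n <- max(length(gly), length(chol))
  nms <- if (length(gly) == n) names(gly) else names(chol)
  gly <- rep_len(gly, n); chol <- rep_len(chol, n)
  out <- rep("unclassified", n)
  out[gly <= 0 & chol <= 0] <- "quiescent"
  out[gly > 0 & gly > chol] <- "glycolytic"
  out[chol > 0 & chol > gly] <- "cholesterol"
  if (any(out == "unclassified"))
    warning(sprintf("%d sample(s) with an exact positive tie left unclassified",
                    sum(out == "unclassified")))
  names(out) <- nms
  out
}

#' Top-50\% immune phenotype split
#'
#' Ranks samples by score descending (ties broken by sample id,
#' lexicographically ascending); the top ceiling(n/2) are "hot", the rest
#' "cold". For 881 distinct scores this yields the 441 / 440 split the
#' convention is pinned to.
#'
#' @param scores named numeric vector (sample_id -> score), length >= 2.
#' @return named character vector, sample_id -> "hot"/"cold", in the input
#'   sample order.
#' @export
assignImmunePhenotype <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 samples to split")
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named by unique sample ids")
  ord <- order(-scores, names(scores), method = "radix")
  nHot <- ceiling(length(scores) / 2)
  pheno <- rep("cold", length(scores))
  pheno[ord[seq_len(nHot)]] <- "hot"
  setNames(pheno, names(scores))
}

#' EGFR-based cohort strata
#'
#' EGFR-mutant samples form their own stratum regardless of immune
#' phenotype; EGFR wild-type samples split into WT-hot / WT-cold. A
#' wild-type sample without a phenotype is an error.
#'
#' @param clinical validated clinical data.frame (see
#'   \code{\link{readClinicalTable}}).
#' @param phenotype named character vector, sample_id -> "hot"/"cold",
#'   covering every EGFR wild-type sample.
#' @return named character vector, sample_id -> stratum in
#'   \{"EGFR-mutant", "WT-hot", "WT-cold"\}.
#' @export
stratifySamples <- function(clinical, phenotype) {
  wt <- clinical$sample_id[clinical$egfr_status == "wild-type"]
  missing <- setdiff(wt, names(phenotype))
  if (length(missing))
    stop(sprintf("EGFR wild-type sample(s) without phenotype: %s",
                 paste(missing, collapse = ", ")))
  out <- ifelse(clinical$egfr_status == "mutant", "EGFR-mutant",
                paste0("WT-", phenotype[clinical$sample_id]))
  setNames(out, clinical$sample_id)
}

#' Full per-sample stratification calls
#'
#' Convenience composition: z-score genes, take per-sample medians of the
#' glycolytic and cholesterol modules, apply the quadrant subtype rule,
#' split the cohort (within EGFR wild-type samples) at the top 50\% of the
#' immune score, and derive strata.
#'
#' @param expr an ExpressionMatrix.
#' @param gly_set,chol_set \code{\linkS4class{GeneSet}}s of the coexpressed
#'   modules.
#' @param immune_scores named numeric vector of per-sample immune
#'   (T-cell-inflamed) scores.
#' @param clinical validated clinical data.frame.
#' @return data.frame per sample: \code{sample_id}, \code{gly_median},
#'   \code{chol_median}, \code{metabolic_subtype}, \code{immune_phenotype},
#'   \code{stratum}.
#' @export
callStrata <- function(expr, gly_set, chol_set, immune_scores, clinical) {
  centered <- zscoreGenes(expr)
  gly <- pathwayMedianScore(centered, gly_set)
  chol <- pathwayMedianScore(centered, chol_set)
  subtype <- assignMetabolicSubtype(gly, chol)
  wt <- clinical$sample_id[clinical$egfr_status == "wild-type"]
  pheno <- assignImmunePhenotype(immune_scores[wt])
  phenoAll <- assignImmunePhenotype(immune_scores)
  stratum <- stratifySamples(clinical, pheno)
  ids <- clinical$sample_id
  data.frame(sample_id = ids, gly_median = gly[ids],
             chol_median = chol[ids], metabolic_subtype = subtype[ids],
             immune_phenotype = phenoAll[ids], stratum = stratum[ids],
             row.names = NULL, stringsAsFactors = FALSE)
}
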