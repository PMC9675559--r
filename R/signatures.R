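# Packaged signature stand-ins. The externally curated resources the analysis
# normally consumes (MSigDB hallmark sets, the 29-signature immune panel, the
# ESTIMATE stromal/immune lists, curated ferroptosis driver/suppressor
# lists, the 18-gene
# T-cell-inflamed signature with weights) cannot be redistributed verbatim;
# the files under extdata/ are small synthetic reconstructions that preserve
# structure (set counts, sizes, realistic symbols) and are labeled as such.

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "MetaboStrat")
  if (!nzchar(p)) stop(sprintf("packaged file not found: %s", file))
  p
}

#' The packaged 18-gene T-cell-inflamed weighted signature
#'
#' A synthetic reconstruction of the 18-gene T-cell-inflamed gene expression
#' profile (GEP): the field-standard gene symbols with plausible weighting
#' coefficients. Scores computed from it are weighted sums of cohort z-scored
#' expression; it is shipped for offline testing, not as the published
#' signature.
#'
#' @return a \code{\linkS4class{WeightedGeneSet}} of 18 genes.
#' @export
tcellInflamedSignature <- function() {
  df <- read.delim(extdataPath("tcell_inflamed_18gene_synthetic.tsv"),
                   stringsAsFactors = FALSE)
  WeightedGeneSet("TCELL_INFLAMED_GEP_18", df$gene, df$weight)
}

#' Packaged 29-signature immune panel (synthetic stand-in)
#'
#' @return a \code{\linkS4class{SignatureCollection}} of 29 immune cell /
#'   pathway signatures with realistic member symbols.
#' @export
immunePanelSignatures <- function() {
  readGmt(extdataPath("immune_signatures_29_synthetic.gmt"))
}

#' Packaged ESTIMATE stromal / immune signatures (synthetic stand-in)
#'
#' @return a \code{\linkS4class{SignatureCollection}} with sets
#'   \code{STROMAL_SIGNATURE} and \code{IMMUNE_SIGNATURE}.
#' @export
estimateSignatures <- function() {
  readGmt(extdataPath("estimate_signatures_synthetic.gmt"))
}

#' Packaged ferroptosis driver / suppressor gene lists (synthetic stand-in)
#'
#' @return a \code{\linkS4class{SignatureCollection}} with sets
#'   \code{FERROPTOSIS_DRIVER} and \code{FERROPTOSIS_SUPPRESSOR}.
#' @export
ferroptosisSignatures <- function() {
  readGmt(extdataPath("ferroptosis_signatures_synthetic.gmt"))
}

#' Packaged statin / immunotherapy meta-analysis study tables
#'
#' Two study tables mirroring the structure of the statin survival
#' meta-analyses: \code{"nsclc"} (16 literature studies plus an in-house
#' cohort; enrollments sum to 63,273 + 101) and \code{"pan_cancer_ici"}
#' (6 ICI studies plus the in-house cohort; enrollments sum to
#' 2,135 + 101 = 2,236). Per-study identities, HRs and enrollment splits are
#' synthetic; only the published totals and study counts are preserved.
#'
#' @param which \code{"pan_cancer_ici"} or \code{"nsclc"}.
#' @return data.frame of study effects as from \code{\link{readMetaTable}}.
#' @export
packagedMetaTable <- function(which = c("pan_cancer_ici", "nsclc")) {
  which <- match.arg(which)
  file <- switch(which,
                 pan_cancer_ici = "statin_ici_pan_cancer_meta_synthetic.csv",
                 nsclc = "statin_nsclc_meta_synthetic.csv")
  readMetaTable(extdataPath(file))
}
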