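# subset a weighted signature to the genes present in a matrix
intersectWeighted <- function(sig, expr) {
  keep <- geneMembers(sig) %in% geneIds(expr)
  if (!any(keep))
    stop(sprintf("no gene of weighted signature '%s' present", setName(sig)))
  if (!all(keep))
    warning(sprintf("weighted signature '%s': %d gene(s) absent from matrix",
                    setName(sig), sum(!keep)))
  WeightedGeneSet(setName(sig), geneMembers(sig)[keep],
                  unname(geneWeights(sig))[keep])
}

#' Run the full metabolic-immune stratification analysis
#'
#' Composes the pipeline end to end: consensus module discovery on the
#' candidate glycolytic and cholesterol genes, per-sample median module
#' scores and quadrant metabolic subtypes, T-cell-inflamed scoring and the
#' top-50\% hot/cold split (within EGFR wild-type samples), EGFR strata,
#' cholesterol / ferroptosis / ESTIMATE / immune-panel signature scores,
#' Kaplan-Meier curves and pairwise log-rank tests across strata, and an
#' optional hazard-ratio meta-analysis. Deterministic under \code{seed}.
#'
#' @param expr an \code{\linkS4class{ExpressionMatrix}}.
#' @param clinical validated clinical data.frame.
#' @param gly_candidates,chol_candidates \code{\linkS4class{GeneSet}}s of
#'   candidate pathway genes from which the coexpressed modules are
#'   discovered.
#' @param tcell_sig weighted T-cell-inflamed signature (default: packaged
#'   18-gene stand-in).
#' @param consensus a \code{\link{consensusParams}} (its seed is overridden
#'   by \code{seed}).
#' @param score a \code{\link{scoreParams}}.
#' @param meta_studies optional study data.frame; when given, fixed and
#'   random-effects pooling, leave-one-out and Egger's test are run.
#' @param outdir optional output directory; when given, result tables are
#'   written as TSV and the run report as JSON.
#' @param seed integer seed recorded in the run report.
#' @return list with \code{modules} (gly/chol GeneSets), \code{calls}
#'   (per-sample stratification data.frame), \code{scores} (signature x
#'   sample matrix), \code{estimate} (ESTIMATE data.frame), \code{survival}
#'   (KM tables and pairwise log-rank results by stratum), \code{meta}
#'   (when requested), and \code{report}.
#' @export
runPipeline <- function(expr, clinical, gly_candidates, chol_candidates,
                        tcell_sig = tcellInflamedSignature(),
                        consensus = consensusParams(),
                        score = scoreParams(),
                        meta_studies = NULL, outdir = NULL, seed = 1L) {
  stopifnot(is(expr, "ExpressionMatrix"))
  clinical <- validateClinicalTable(clinical)
  if (!setequal(clinical$sample_id, sampleIds(expr)))
    stop("clinical table and expression matrix cover different samples")

  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  modules <- stage("module discovery", {
    discover <- function(cands, nm, offset) {
      genes <- intersect(geneMembers(cands), geneIds(expr))
      if (length(genes) < consensus$k)
        stop(sprintf("too few candidate genes present for '%s'",
                     setName(cands)))
      prm <- consensusParams(reps = consensus$reps,
                             p_item = consensus$p_item,
                             p_feature = consensus$p_feature,
                             k = consensus$k, seed = seed + offset)
      res <- consensusCluster(expr, genes, prm)
      list(result = res,
           module = selectCoexpressed(res, expr, name = nm))
    }
    list(gly = discover(gly_candidates, "COEXPRESSED_GLYCOLYTIC", 11L),
         chol = discover(chol_candidates, "COEXPRESSED_CHOLESTEROL", 23L))
  })

  tcell <- stage("T-cell-inflamed scoring", {
    weightedSignatureScore(expr, intersectWeighted(tcell_sig, expr))
  })

  calls <- stage("stratification", {
    callStrata(expr, modules$gly$module, modules$chol$module, tcell,
               clinical)
  })

  scores <- stage("signature scoring", {
    sets <- c(list(modules$chol$module, modules$gly$module),
              geneSets(ferroptosisSignatures()),
              geneSets(immunePanelSignatures()))
    suppressWarnings(
      scoreSignatures(expr, SignatureCollection(sets), score))
  })
  estimate <- stage("ESTIMATE scoring", {
    sigs <- estimateSignatures()
    stro <- sigs[["STROMAL_SIGNATURE"]]
    immu <- sigs[["IMMUNE_SIGNATURE"]]
    if (any(geneMembers(stro) %in% geneIds(expr)) &&
        any(geneMembers(immu) %in% geneIds(expr)))
      estimateScores(expr, stro, immu, alpha = score$alpha)
    else NULL
  })

  surv <- stage("survival analysis", {
    records <- clinical[, c("sample_id", "os_time", "os_event")]
    byStratum <- setNames(calls$stratum, calls$sample_id)
    bySubtype <- setNames(calls$metabolic_subtype, calls$sample_id)
    pairLogrank <- function(groups) {
      lev <- sort(unique(groups))
      if (length(lev) < 2L) return(NULL)
      pairs <- combn(lev, 2L)
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        keep <- groups %in% pairs[, i]
        lr <- logrankTest(records[records$sample_id %in%
                                    names(groups)[keep], , drop = FALSE],
                          groups[keep])
        data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
                   chi2 = lr$chi2, df = lr$df, p = lr$p,
                   stringsAsFactors = FALSE)
      }))
    }
    km <- lapply(split(records, byStratum[records$sample_id]), kaplanMeier)
    list(km_by_stratum = km,
         logrank_strata = pairLogrank(byStratum),
         logrank_subtypes = pairLogrank(bySubtype),
         omnibus_strata = logrankTest(records, byStratum))
  })

  meta <- NULL
  if (!is.null(meta_studies)) {
    meta <- stage("meta-analysis", {
      list(fixed = poolEffects(meta_studies, "fixed"),
           random = poolEffects(meta_studies, "random-DL"),
           leave_one_out = leaveOneOut(meta_studies),
           egger = if (nrow(meta_studies) >= 3)
             eggerTest(meta_studies)[c("intercept", "intercept_se",
                                       "t", "p")]
           else NULL)
    })
  }

  report <- list(
    package_version = as.character(utils::packageVersion("MetaboStrat")),
    seed = seed,
    parameters = list(consensus = unclass(consensus)[
      c("reps", "p_item", "p_feature", "k", "linkage")],
      score = unclass(score)),
    n_samples = nrow(clinical),
    module_sizes = list(
      glycolytic = length(geneMembers(modules$gly$module)),
      cholesterol = length(geneMembers(modules$chol$module))),
    subtype_counts = as.list(table(calls$metabolic_subtype)),
    phenotype_counts = as.list(table(calls$immune_phenotype)),
    stratum_counts = as.list(table(calls$stratum)))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) write.table(df, file.path(outdir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    wt(calls, "sample_calls.tsv")
    wt(data.frame(signature = rownames(scores), scores,
                  check.names = FALSE), "signature_scores.tsv")
    if (!is.null(estimate)) wt(estimate, "estimate_scores.tsv")
    if (!is.null(surv$logrank_strata)) wt(surv$logrank_strata,
                                          "logrank_strata.tsv")
    if (!is.null(meta)) wt(meta$leave_one_out, "meta_leave_one_out.tsv")
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(modules = list(glycolytic = modules$gly$module,
                      cholesterol = modules$chol$module,
                      consensus_gly = modules$gly$result,
                      consensus_chol = modules$chol$result),
       tcell_score = tcell, calls = calls, scores = scores,
       estimate = estimate, survival = surv, meta = meta, report = report)
}
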