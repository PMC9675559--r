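# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards, so generators are pure functions of their config.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for a synthetic expression cohort
#'
#' Describes a cohort with two planted coexpressed metabolic modules
#' (glycolytic / cholesterol), independent noise genes, a latent immune
#' axis acting on the packaged 18-gene T-cell-inflamed signature, and an
#' EGFR-mutant flag.
#'
#' @param n_samples cohort size (>= 3; the three subtypes must be plantable).
#' @param n_glycolytic_genes,n_cholesterol_genes module sizes; defaults 16 and
#'   13 mirror the coexpressed module sizes the stratification targets.
#' @param n_noise_genes independent background genes.
#' @param module_effect_size separation (in module-activity units) between the
#'   high and low state of each planted module.
#' @param immune_effect_size shift added to the 18 signature genes in planted
#'   immuno-hot samples.
#' @param noise_sd per-gene Gaussian noise SD (> 0).
#' @param egfr_mutant_fraction expected EGFR-mutant fraction, in [0, 1].
#' @param seed integer RNG seed; the generator is a pure function of the
#'   config including the seed.
#' @return a validated list of class \code{cohortConfig}.
#' @export
cohortConfig <- function(n_samples = 300L, n_glycolytic_genes = 16L,
                         n_cholesterol_genes = 13L, n_noise_genes = 100L,
                         module_effect_size = 3, immune_effect_size = 3,
                         noise_sd = 1, egfr_mutant_fraction = 0.087,
                         seed = 1L) {
  counts <- c(n_samples, n_glycolytic_genes, n_cholesterol_genes,
              n_noise_genes)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_samples < 3) stop("n_samples < 3: cannot plant 3 subtypes")
  if (module_effect_size < 0 || immune_effect_size < 0)
    stop("effect sizes must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (egfr_mutant_fraction < 0 || egfr_mutant_fraction > 1)
    stop("egfr_mutant_fraction must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_glycolytic_genes = as.integer(n_glycolytic_genes),
                 n_cholesterol_genes = as.integer(n_cholesterol_genes),
                 n_noise_genes = as.integer(n_noise_genes),
                 module_effect_size = module_effect_size,
                 immune_effect_size = immune_effect_size,
                 noise_sd = noise_sd,
                 egfr_mutant_fraction = egfr_mutant_fraction,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Generate a synthetic cohort with planted metabolic and immune structure
#'
#' Samples are assigned round-robin to the three metabolic subtypes
#' (quiescent / glycolytic / cholesterol) and alternately to the hot / cold
#' immune phenotypes. Each module gene equals the subtype-dependent latent
#' module activity (+effect/2 in the matching subtype, -effect/2 otherwise)
#' plus Gaussian noise; the quiescent subtype is low on both modules. The 18
#' T-cell-inflamed signature genes are shifted up by \code{immune_effect_size}
#' in planted-hot samples. Noise genes are independent Gaussians. Survival
#' follows exponential proportional hazards tied to subtype and phenotype.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param group_log_hr named log-hazard offsets applied on top of baseline;
#'   names are \code{subtype:phenotype} groups (see Details in the vignette).
#'   Default plants worse survival for cholesterol-cold tumors.
#' @param baseline_rate exponential baseline hazard per month.
#' @param censor_prob independent censoring probability.
#' @return list with \code{expression} (ExpressionMatrix), \code{clinical}
#'   (validated clinical data.frame), \code{truth} (per-sample planted labels
#'   and latent activities), and \code{candidates} (SignatureCollection of
#'   candidate glycolytic / cholesterol gene sets: the planted module genes
#'   diluted with noise genes, as input for module discovery).
#' @export
generateExpressionCohort <- function(config,
                                     group_log_hr = NULL,
                                     baseline_rate = 0.02,
                                     censor_prob = 0.3) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$n_samples
  subtypes <- rep_len(c("quiescent", "glycolytic", "cholesterol"), n)
  phenotypes <- rep_len(c("hot", "cold"), n)
  sampleIds <- sprintf("S%04d", seq_len(n))
  glyGenes <- sprintf("GLY%03d", seq_len(config$n_glycolytic_genes))
  choGenes <- sprintf("CHO%03d", seq_len(config$n_cholesterol_genes))
  immuneSig <- tcellInflamedSignature()
  immGenes <- geneMembers(immuneSig)
  noiseGenes <- sprintf("NSE%04d", seq_len(config$n_noise_genes))
  genes <- c(glyGenes, choGenes, immGenes, noiseGenes)

  e <- config$module_effect_size
  aGly <- ifelse(subtypes == "glycolytic", e / 2, -e / 2)
  aCho <- ifelse(subtypes == "cholesterol", e / 2, -e / 2)
  aImm <- ifelse(phenotypes == "hot", config$immune_effect_size, 0)

  expr <- withSeed(config$seed, {
    m <- matrix(rnorm(length(genes) * n, sd = config$noise_sd),
                nrow = length(genes), ncol = n,
                dimnames = list(genes, sampleIds))
    m[glyGenes, ] <- m[glyGenes, , drop = FALSE] +
      matrix(aGly, length(glyGenes), n, byrow = TRUE)
    m[choGenes, ] <- m[choGenes, , drop = FALSE] +
      matrix(aCho, length(choGenes), n, byrow = TRUE)
    m[immGenes, ] <- m[immGenes, , drop = FALSE] +
      matrix(aImm, length(immGenes), n, byrow = TRUE)
    m
  })
  egfr <- withSeed(config$seed + 101L, {
    ifelse(rbinom(n, 1L, config$egfr_mutant_fraction) == 1L,
           "mutant", "wild-type")
  })

  if (is.null(group_log_hr)) {
    group_log_hr <- c("quiescent:hot" = 0, "quiescent:cold" = 0.2,
                      "glycolytic:hot" = 0.4, "glycolytic:cold" = 0.2,
                      "cholesterol:hot" = 0.2, "cholesterol:cold" = 0.7)
  }
  groups <- setNames(paste(subtypes, phenotypes, sep = ":"), sampleIds)
  surv <- generateSurvivalTimes(groups, group_log_hr,
                                baseline_rate = baseline_rate,
                                censor_prob = censor_prob,
                                seed = config$seed + 202L)
  clinical <- validateClinicalTable(
    data.frame(sample_id = sampleIds, egfr_status = egfr,
               os_time = surv$os_time, os_event = surv$os_event,
               stringsAsFactors = FALSE))
  truth <- data.frame(sample_id = sampleIds, subtype = subtypes,
                      phenotype = phenotypes, gly_activity = aGly,
                      chol_activity = aCho, immune_activity = aImm,
                      stringsAsFactors = FALSE)
  nDilute <- min(20L, config$n_noise_genes)
  candidates <- SignatureCollection(list(
    GeneSet("GLYCOLYSIS_CANDIDATES",
            c(glyGenes, noiseGenes[seq_len(nDilute)])),
    GeneSet("CHOLESTEROL_CANDIDATES",
            c(choGenes, noiseGenes[config$n_noise_genes -
                                     seq_len(nDilute) + 1L]))))
  list(expression = ExpressionMatrix(expr), clinical = clinical,
       truth = truth, candidates = candidates)
}

#' Generate exponential proportional-hazards survival times
#'
#' Event times are exponential with rate
#' \code{baseline_rate * exp(group_log_hr[group])}. Each subject is censored
#' independently with probability \code{censor_prob}; a censored subject is
#' observed at a Uniform(0, T) time before its latent event time T.
#'
#' @param groups named character vector, sample_id -> group label.
#' @param group_log_hr named numeric, group label -> log hazard ratio; every
#'   group occurring in \code{groups} must be covered.
#' @param baseline_rate baseline exponential hazard, > 0.
#' @param censor_prob censoring probability in [0, 1].
#' @param seed integer RNG seed.
#' @return data.frame with \code{sample_id}, \code{os_time}, \code{os_event}.
#' @export
generateSurvivalTimes <- function(groups, group_log_hr, baseline_rate,
                                  censor_prob = 0, seed = 1L) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (censor_prob < 0 || censor_prob > 1)
    stop("censor_prob must lie in [0, 1]")
  missing <- setdiff(unique(groups), names(group_log_hr))
  if (length(missing))
    stop(sprintf("no log-hazard specified for group(s): %s",
                 paste(missing, collapse = ", ")))
  n <- length(groups)
  rates <- baseline_rate * exp(unname(group_log_hr[groups]))
  withSeed(seed, {
    eventTime <- rexp(n, rate = rates)
    censored <- runif(n) < censor_prob
    obsTime <- ifelse(censored, runif(n) * eventTime, eventTime)
    data.frame(sample_id = names(groups), os_time = obsTime,
               os_event = as.integer(!censored), stringsAsFactors = FALSE)
  })
}

#' Configuration for simulated hazard-ratio meta-analyses
#'
#' @param k_studies number of studies (>= 1).
#' @param true_log_hr common true log hazard ratio.
#' @param tau2 between-study variance (>= 0).
#' @param n_range integer interval (length 2) for per-study enrollment.
#' @param seed integer RNG seed.
#' @return validated list of class \code{metaSimConfig}.
#' @export
metaSimConfig <- function(k_studies = 16L, true_log_hr = 0, tau2 = 0,
                          n_range = c(50L, 500L), seed = 1L) {
  if (k_studies < 1) stop("k_studies must be >= 1")
  if (tau2 < 0) stop("tau2 must be >= 0")
  if (length(n_range) != 2L || n_range[1] > n_range[2] || n_range[1] < 2)
    stop("n_range must be an increasing integer interval with min >= 2")
  structure(list(k_studies = as.integer(k_studies),
                 true_log_hr = true_log_hr, tau2 = tau2,
                 n_range = as.integer(n_range), seed = as.integer(seed)),
            class = "metaSimConfig")
}

#' Simulate study-level log hazard ratios with heterogeneity
#'
#' Per study i: enrollment n_i is uniform on \code{n_range}; the within-study
#' standard error follows the stated decreasing function se_i = 2 / sqrt(n_i);
#' the study's true effect is \code{true_log_hr} + Normal(0, tau2); the
#' observed log HR adds Normal(0, se_i^2) sampling noise. Studies alternate
#' between the "immunotherapy" and "non-immunotherapy" subgroup tags.
#'
#' @param config a \code{\link{metaSimConfig}}.
#' @return data.frame with \code{study_id}, \code{log_hr}, \code{se},
#'   \code{n}, \code{subgroup}.
#' @export
generateMetaStudies <- function(config) {
  stopifnot(inherits(config, "metaSimConfig"))
  k <- config$k_studies
  withSeed(config$seed, {
    n <- sample(seq(config$n_range[1], config$n_range[2]), k, replace = TRUE)
    se <- 2 / sqrt(n)
    theta <- config$true_log_hr + rnorm(k, sd = sqrt(config$tau2))
    obs <- theta + rnorm(k, sd = se)
    data.frame(study_id = sprintf("STUDY%02d", seq_len(k)), log_hr = obs,
               se = se, n = n,
               subgroup = rep_len(c("immunotherapy", "non-immunotherapy"), k),
               stringsAsFactors = FALSE)
  })
}
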