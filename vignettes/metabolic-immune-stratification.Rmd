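---
title: "Metabolic-immune stratification of bulk tumor transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic-immune stratification of bulk tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboStrat)
```

## The problem this package addresses

A large fraction of EGFR wild-type non-small-cell lung cancers are
"immuno-cold" — poorly infiltrated by T cells — and respond badly to immune
checkpoint blockade. Tumor metabolism is one axis along which hot and cold
tumors differ: glycolysis and cholesterol biosynthesis are frequently
rewired in tumors, and the balance between the two carries prognostic and
immunological information. MetaboStrat implements a stratification
framework that places each tumor of a bulk expression cohort on a
glycolysis/cholesterol metabolic axis and a T-cell-inflamed immune axis,
then asks how the resulting strata differ in survival and signature
activity, and finally pools study-level hazard ratios for an intervention
(statin use alongside checkpoint blockade) across published cohorts.

The pipeline has five stages, each usable on its own:

1. **Module discovery** (`consensusCluster`, `selectCoexpressed`): from
   candidate glycolysis and cholesterol-synthesis genes, find the subsets
   that are actually coexpressed in the cohort, by resampled consensus
   hierarchical clustering.
2. **Metabolic subtyping** (`zscoreGenes`, `pathwayMedianScore`,
   `assignMetabolicSubtype`): per-sample median of the z-scored module
   genes, then a quadrant rule — quiescent (both medians at or below 0),
   glycolytic (glycolytic median positive and dominant), cholesterol
   (cholesterol median positive and dominant).
3. **Immune phenotyping and strata** (`weightedSignatureScore`,
   `assignImmunePhenotype`, `stratifySamples`): an 18-gene weighted
   T-cell-inflamed score, a top-50% hot/cold split, and EGFR-aware strata
   (EGFR-mutant, WT-hot, WT-cold).
4. **Signature scoring** (`ssgseaScore`, `scoreSignatures`,
   `estimateScores`, `oraEnrichment`): single-sample GSEA for arbitrary
   signatures (cholesterol score, ferroptosis driver/suppressor scores, a
   29-signature immune panel), ESTIMATE stromal/immune/purity scores, and
   hypergeometric over-representation analysis.
5. **Inference** (`kaplanMeier`, `logrankTest`, `compareGroups`,
   `chisqIndependence`, `poolEffects`, `leaveOneOut`, `eggerTest`):
   survival comparison across strata and hazard-ratio meta-analysis with
   heterogeneity, subgroup pooling, leave-one-out sensitivity and Egger's
   asymmetry test.

`runPipeline()` composes stages 1–5 and writes TSV tables plus a JSON run
report sufficient to re-run bit-identically.

## Models and conventions

### Consensus clustering

Genes are clustered on the distance `1 - rho_s`, with `rho_s` the Spearman
rank correlation across samples, using Ward.D2 linkage. Per repetition
(default 100), 80% of genes and 100% of samples are drawn without
replacement; the subsample is clustered and cut at `k = 5`. The consensus
index of a gene pair is its co-clustering count divided by its co-sampling
count. Final labels cut a Ward.D2 tree of `1 - consensus` at the same `k`.

Three conventions are the package's own, because a named tool leaves them
open:

* **Ward.D2 on a non-Euclidean distance.** The Lance–Williams update is
  applied to the correlation distance exactly as `stats::hclust` does
  (squaring the input distances internally); this matches the referenced
  algorithm's observed behavior on this metric even though the distance is
  not Euclidean.
* **Items are genes.** Resampling at `p_item = 0.8` is over genes, with
  `p_feature` controlling the sample dimension; both are exposed in
  `consensusParams` so the alternative reading is one argument away.
* **Module selection.** How a "coexpressed" module is extracted from a
  `k = 5` solution is not fixed by the procedure, so `selectCoexpressed`
  uses a declared rule: among clusters of at least `min_size = 5` genes,
  take the one with the highest mean pairwise Spearman correlation,
  breaking exact ties toward the smaller cluster label. On planted-module
  cohorts this recovers the planted genes exactly (see the test suite).

### Subtyping and the immune split

Median module expression only discriminates subtypes if 0 is anchored
somewhere meaningful. The package z-scores each gene across the cohort
first, so 0 is cohort-average expression; this follows the precedent of
the glycolytic/cholesterol stratification frameworks this one adapts. An
exact positive tie between the two medians is left `unclassified` with a
warning rather than silently resolved — ties are measure-zero for
continuous scores, and the quadrant rule genuinely does not cover them.

The hot/cold split takes the top `ceiling(n/2)` scores as hot, ties broken
lexicographically by sample id. The ceiling convention is pinned by the
arithmetic of an 881-sample wild-type cohort splitting 441/440. The split
used for strata is computed **within EGFR wild-type samples** — the same
arithmetic implies the split was not done on the full cohort — while the
`immune_phenotype` column of `callStrata` reports the full-cohort split so
every sample carries a phenotype.

### ssGSEA

Per sample, genes are ranked by decreasing expression with average ranks
for ties. Walking down that ranking, the score sums the difference between
the in-set cumulative weight — weights are the rank statistic raised to
`alpha = 0.25`, normalized to sum 1 over set members — and the out-of-set
cumulative fraction. With `normalize = TRUE` the score matrix is divided
by its global range. Both `alpha` and the normalization follow the
conventional defaults of the widely used ssGSEA implementation and are
exposed in `scoreParams` because the procedure itself does not fix them.
The raw score depends only on within-sample ranks, hence is invariant
under strictly monotone per-sample transforms, and there is no
cross-sample leakage except the optional global normalization.

### ESTIMATE

Stromal and immune scores are raw (unnormalized) ssGSEA scores of the two
ESTIMATE signatures; their sum is the ESTIMATE score and tumor purity
applies the published calibration
`purity = cos(0.6049872018 + 0.0001467884 * estimate_score)`. That
calibration was fitted on microarray data; applied to other platforms it
can leave [0, 1], so out-of-range purities are flagged
(`purity_in_range`), never clipped.

### The T-cell-inflamed score

The score is a weighted sum of cohort z-scored expression over 18 genes.
Whether the published score z-scores expression first is not stated in the
procedure this reproduces; the weighted-sum-of-z form follows the original
signature's convention and is declared here. The packaged gene/weight
table is a **synthetic reconstruction** (field-standard symbols, plausible
weights) shipped so the pipeline runs offline; no test depends on the
specific weights, only on structural properties of the scoring.

### Over-representation analysis

Hypergeometric upper tail `P(X >= k)` per term, after intersecting terms
with the universe and filtering to sizes in `[5, 5000]`. Significance is
raw `p <= 0.05`, as the workflow this mirrors states, with BH-adjusted `q`
reported alongside.

### Survival and group tests

Kaplan–Meier and the log-rank test go through the survival package
(`survfit`, `survdiff` with `rho = 0`), i.e. the standard
observed-minus-expected statistic with hypergeometric variance at tied
event times, and chi-square p at `groups - 1` df. All tests are
two-sided. `compareGroups` maps onto pooled-variance Student's t,
Mann–Whitney U, one-way ANOVA + Tukey HSD, or Kruskal–Wallis + Dunn; Dunn's
z uses the tie-corrected rank-sum form and adjusts with BH by default (the
post-hoc adjustment is not fixed by the source workflow; the flag
`adjust` exposes it).

### Meta-analysis

Fixed-effect pooling uses inverse-variance weights `w_i = 1/se_i^2`;
random effects use DerSimonian–Laird
`tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with re-weighting
`1/(se_i^2 + tau^2)`. `Q` and `I^2 = max(0, (Q - df)/Q) * 100` are always
computed from the fixed-effect weights, so DL truncation at `Q <= df`
collapses the random-effects result onto the fixed one exactly. Whether
the original analysis pooled in fixed or random mode is unstated, so both
are computed, with random-DL the default — the norm for clinically
heterogeneous observational studies. CIs use the normal quantile
1.959964 (no Knapp–Hartung adjustment), matching common usage of the
named software; HR/CI inputs are converted with the same quantile so the
conversion round-trips. Egger's test regresses the standardized effect on
precision by OLS, with two-sided t-based p at `k - 2` df; it requires at
least 3 studies and non-constant standard errors.

## The synthetic-data generator

`generateExpressionCohort` emulates the statistical structure the analysis
assumes, not RNA-Seq data per se:

* samples are assigned round-robin to the three metabolic subtypes and
  alternately to hot/cold, so planted classes are balanced;
* each module gene equals a subtype-dependent latent activity (+e/2 in the
  matching subtype, -e/2 otherwise, `e = module_effect_size`, default 3)
  plus Gaussian noise (`noise_sd`, default 1). The quiescent subtype is
  low on both modules, mirroring the quadrant semantics;
* the 18 signature genes gain `immune_effect_size` (default 3) in hot
  samples; noise genes are independent Gaussians;
* the EGFR-mutant flag is Bernoulli at `egfr_mutant_fraction`
  (default 0.087, the mutant share of an 881 + 77 cohort), independent of
  subtype;
* survival is exponential proportional hazards: rate
  `baseline_rate * exp(log HR of the subtype:phenotype group)`, defaults
  planting the worst prognosis in cholesterol-cold tumors. Censoring is a
  per-subject Bernoulli(`censor_prob`) flag; a censored subject is
  observed at a Uniform(0, T) fraction of its latent event time, which
  honors "censored with probability p" exactly and is identical across
  groups.

`generateMetaStudies` draws per-study enrollment uniformly on `n_range`,
sets the within-study standard error by the stated decreasing function
`se = 2/sqrt(n)`, adds Normal(0, tau2) between-study heterogeneity to the
true log HR and Normal(0, se^2) sampling noise.

All generators are pure functions of their configuration: the seed is part
of the config, sub-streams are derived from fixed offsets, and the
caller's RNG state is restored afterwards, so repeated calls are
bit-identical and never perturb surrounding code.

**What the generator does not model** — and hence what passing tests do
not show about real data: negative-binomial count noise and library-size
effects, batch structure, correlated noise between modules, gene-gene
correlation among noise genes, informative censoring, and non-proportional
hazards. Recovery accuracies on these cohorts are upper bounds for what
the same pipeline achieves on real RNA-Seq.

## Calibration checks and problem sizes

The package's own calibration suite (mirrored by
`scripts/acceptance.R`) uses these problem sizes, chosen to make
Monte-Carlo error small relative to the quantities checked while keeping
the default test run quick:

* ssGSEA equivalence to a direct-summation oracle: 200 random matrices of
  up to 10 genes by 5 samples (agreement to 1e-9);
* consensus recovery: two planted orthogonal 10-gene modules over 50
  samples at signal 5 (ARI 1, within-module consensus at least 0.9), and a
  planted 16-gene module among 50 noise genes at `k = 5`;
* log-rank size: 1,000 null two-group cohorts of n = 100 with 20%
  censoring (rejection within 5% plus/minus 1.5%);
* meta-analysis calibration: 2,000 simulated 16-study meta-analyses at
  `tau2 = 0` (Q-test size and fixed-effect CI coverage within two
  Monte-Carlo standard errors of 5% and 95%);
* planted-truth recovery: a 300-sample cohort at the default effect sizes
  (subtype and phenotype accuracy at least 0.95).

## Known limitations

* The packaged signature files (hallmark-style candidates, the 29-panel,
  ESTIMATE lists, ferroptosis lists, the 18-gene weighted signature) are
  labeled synthetic reconstructions; analyses of real cohorts should
  substitute the curated originals via `readGmt`/`WeightedGeneSet`.
* Subtype counts and survival curves of any specific published cohort are
  not reproducible without that cohort's expression and clinical data;
  the package reproduces the procedure and its conventions, and verifies
  them on synthetic cohorts with known truth.
* `selectCoexpressed` is a declared convention, not a published rule; at
  moderate signal the selected cluster can absorb an occasional noise
  gene.
* Cox modeling and multivariable adjustment are out of scope; survival
  comparisons are unadjusted, as in the workflow this reproduces.
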