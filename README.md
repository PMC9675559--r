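# MetaboStrat

Metabolic–immune stratification of bulk tumor expression cohorts, built
for the setting of EGFR wild-type non-small-cell lung cancer: many of
these tumors are "immuno-cold" (few infiltrating T cells) and respond
poorly to immune checkpoint blockade, and the glycolysis /
cholesterol-synthesis balance is a metabolic axis along which hot and
cold tumors differ. MetaboStrat is for computational biologists who want
to run — or stress-test — that stratification on their own cohorts, or on
fully synthetic cohorts with known planted truth.

## What it computes

* **Coexpressed metabolic modules** by resampled consensus hierarchical
  clustering of candidate genes: per repetition, 80% of genes are
  subsampled, clustered with Ward.D2 on the distance *d*(i,j) = 1 −
  ρ<sub>s</sub>(i,j) (Spearman correlation across samples) and cut at
  *k* = 5; the consensus matrix C<sub>ij</sub> = (co-cluster count)/(co-sample
  count) is then itself clustered to give final module assignments.
* **Metabolic subtypes** from per-sample medians of z-scored module genes
  (m<sub>gly</sub>, m<sub>chol</sub>), by the quadrant rule: quiescent
  (m<sub>gly</sub> ≤ 0 and m<sub>chol</sub> ≤ 0), glycolytic
  (m<sub>gly</sub> > 0 and m<sub>gly</sub> > m<sub>chol</sub>), cholesterol
  (m<sub>chol</sub> > 0 and m<sub>chol</sub> > m<sub>gly</sub>).
* **Immune phenotype and strata**: an 18-gene T-cell-inflamed score
  Σ<sub>g</sub> w<sub>g</sub> z<sub>g</sub> (weighted sum of cohort
  z-scores), a top-⌈n/2⌉ hot/cold split, and EGFR-aware strata
  (EGFR-mutant, WT-hot, WT-cold).
* **Signature scores**: single-sample GSEA (rank weight exponent
  α = 0.25, optional global range normalization), ESTIMATE
  stromal/immune scores with the published purity calibration
  purity = cos(0.6049872018 + 0.0001467884·ESTIMATE), ferroptosis
  driver/suppressor and 29-signature immune-panel scores, and
  hypergeometric over-representation analysis (term sizes 5–5000,
  P ≤ 0.05 with BH q alongside).
* **Inference**: Kaplan–Meier curves and log-rank tests across strata;
  t / Mann–Whitney / ANOVA+Tukey / Kruskal–Wallis+Dunn group comparisons;
  Pearson χ²; and hazard-ratio meta-analysis — fixed-effect
  (inverse-variance) and DerSimonian–Laird random-effects pooling with
  Q, I², τ², subgroup filtering, leave-one-out sensitivity and Egger's
  regression test.
* **Synthetic cohorts** (`generateExpressionCohort`,
  `generateSurvivalTimes`, `generateMetaStudies`) with planted subtypes,
  immune phenotypes, proportional-hazards survival and study-level
  heterogeneity, so the whole pipeline is testable offline with known
  truth.

The packaged gene-set files (18-gene weighted signature, 29-signature
panel, ESTIMATE and ferroptosis lists, meta-analysis study tables) are
synthetic stand-ins — structurally faithful, clearly labeled — so that
nothing is downloaded at build or test time.

## Worked example

```r
library(MetaboStrat)

cohort <- generateExpressionCohort(cohortConfig(n_samples = 300, seed = 7))
res <- runPipeline(cohort$expression, cohort$clinical,
                   cohort$candidates[["GLYCOLYSIS_CANDIDATES"]],
                   cohort$candidates[["CHOLESTEROL_CANDIDATES"]],
                   meta_studies = packagedMetaTable("pan_cancer_ici"),
                   seed = 7)

unlist(res$report$subtype_counts)
#> cholesterol  glycolytic   quiescent
#>         100         100         100
unlist(res$report$stratum_counts)
#> EGFR-mutant     WT-cold      WT-hot
#>          16         142         142
head(res$calls, 3)
#>   sample_id gly_median chol_median metabolic_subtype immune_phenotype stratum
#> 1     S0001 -0.4252426  -0.3069684         quiescent              hot  WT-hot
#> 2     S0002  1.2348946  -0.3725824        glycolytic             cold WT-cold
#> 3     S0003 -0.7973708   1.4295287       cholesterol              hot  WT-hot
res$meta$random
#> MetaResult (random-DL, k = 7)
#>   pooled HR 0.743 [0.651, 0.847]
#>   Q = 4.839 (df = 6), I2 = 0.0%, tau2 = 0.0000
```

The pipeline discovered the two planted coexpressed modules (16 and 13
genes), recovered the planted three-way subtype split exactly (100/100/100),
split the 284 EGFR wild-type samples 142/142 into hot and cold, and pooled
the packaged synthetic ICI study table to a random-effects hazard ratio of
0.74 (statin use associated with longer survival) with no detected
heterogeneity. `res$survival$logrank_strata` holds the pairwise log-rank
tests between strata, and passing `outdir =` writes every table as TSV
plus a JSON run report that records seed and parameters for bit-identical
re-runs.

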