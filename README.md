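# refeedomics

Statistical machinery for longitudinal multi-omics intervention trials in
which changes in antihypertensive medication confound the biological signal
— the setting of fasting / DASH-diet studies in metabolic-syndrome patients,
where each subject contributes stool microbiome, gut functional-module,
immune-cell and clinical measurements at baseline (V1), one week (V2) and
three months (V3).

The package is aimed at analysts of such repeated-measures cohorts and
implements, as tested reusable components:

* **Medication-deconfounded contrast screening.** For each feature, a
  Gaussian likelihood-ratio test of the nested linear models
  `y ~ age + sex + patient + normalized drug doses` versus the same model
  plus visit (BH FDR < 0.1 within each measurement space), followed by
  unpaired two-sided Mann–Whitney post-hoc tests per visit pair (BH over
  the three contrasts, FDR < 0.05), with the signed Cliff's delta
  `(#{x>y} − #{x<y})/nm` as effect size. Medication doses are normalized so
  an unchanged regimen is 1, a discontinuation 0.
* **Diversity and ordination.** Richness, Shannon, evenness, Simpson,
  inverse Simpson and bias-corrected Chao1; Bray–Curtis and Euclidean
  distances; principal-coordinates analysis; and PERMANOVA whose
  permutations are restricted to within-donor relabelings, with
  `p = (1 + #{F* ≥ F}) / (1 + B)`.
* **Cross-space correlation triplets.** Pooled average-rank Spearman
  screening between clinical, immune and microbiome spaces, a same-donor
  mixed-model post-hoc (rank response ~ rank predictor + (1 | subject), ML
  likelihood ratio, larger of the two directional p-values), and assembly
  of phenotype–immune–microbiome triplets with at least two robust edges
  and one intervention-affected member.
* **Responder stratification and leakage-safe prediction.** Responders are
  subjects whose 24-h ambulatory systolic pressure improved without a
  medication increase (or whose medication dropped without a pressure
  rise). Prediction uses leave-one-subject-out cross-validation with
  fold-internal z-scoring, fold-internal forward-stepwise selection by
  likelihood-ratio p-value, and a no-intercept ridge logistic model
  minimizing `½‖w‖² + C Σ log(1 + exp(−ỹ x·w))`, C = 1; plus cross-cohort
  transfer of a single trained model.
* **A synthetic cohort generator** (`simulateCohort`) producing
  compositional taxon counts, continuous module/immune/clinical tables, a
  medication ledger and ground truth for every planted signal — effects
  calibrated to target Cliff's deltas, medication-confounded features,
  correlated cross-space triplets and a responder blood-pressure mixture —
  so every stage above is testable end to end.

## Worked example

```r
library(refeedomics)

set.seed(42)
effects <- lapply(1:20, function(i)
  plantedEffect(NA, "taxa", "reversible", sample(c(-0.6, 0.6), 1)))
cohort <- simulateCohort(cohortDesign(planted_effects = effects, seed = 42))
cohort
#> SyntheticCohort: 70 subjects x 3 visits (210 samples)
#>   arms: DASH=35, fasting+DASH=35
#>   tables: taxa 200, modules 80, immune 120, clinical 12 features
#>   truth: 20 differential, 20 confounded, 0 triplets planted

meta <- cohortMetadata(cohort)
fasting <- meta[meta$arm == "fasting+DASH", ]
meds <- normalizeMedication(cohortMedication(cohort), visits = c("V1", "V2", "V3"))

screen <- runContrastScreen(cohortTable(cohort, "taxa"), fasting, meds)
truth <- cohortTruth(cohort)$differential_features
cat("flagged:", length(contrastHits(screen)),
    "| planted recovered:", sum(truth$feature_id %in% contrastHits(screen)), "of 20\n")
#> flagged: 22 | planted recovered: 18 of 20

head(subset(screen, significant & contrast == "V1-V2",
            select = c(feature_id, q_lrt, cliffs_delta, q_mwu)), 3)
#>     feature_id      q_lrt cliffs_delta        q_mwu
#> 1    taxon_001 0.01962926   -0.6538776 7.841098e-06
#> 4    taxon_002 0.01248767    0.2228571 1.100524e-01
#> 82   taxon_028 0.04760696   -0.6946939 1.788650e-06
```

The screen recovers 18 of the 20 planted fasting effects; `q_lrt` is the
within-space BH-adjusted likelihood-ratio q-value and `cliffs_delta` the
signed V1→V2 effect size (negative = depleted during fasting). The 20
medication-confounded taxa are not among the hits, although a naive
Mann–Whitney screen flags almost all of them (`marginalMwu`).

```r
rar <- rarefyTable(cohortTable(cohort, "taxa"), depth = "auto", seed = 1)
d <- betaDistance(rar[fasting$sample_id, ], "bray-curtis")
permanovaStratified(d, fasting$visit, fasting$subject_id, 999, seed = 1)[c("pseudo_F", "p_value")]
#> $pseudo_F
#> [1] 10.37911
#> $p_value
#> [1] 0.001

resp <- stratifyResponders(fasting, meds)
tapply(resp$delta_sbp, resp$label, median)
#> non-responder     responder
#>           1.1          -6.8
```

The planted community shift across visits is detected at the permutation
floor (p = 0.001 with 999 within-donor permutations), and the responder
stratification separates a median 24-h systolic drop of 6.8 mmHg from a
flat non-responder group.

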