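# mixdose

Radiation biodosimetry for **mixed neutron + photon exposures** from
multi-omic biomarker panels.

After a nuclear accident or malicious detonation, absorbed dose must be
reconstructed from biology, not from dosimeters nobody was wearing — and
realistic exposures are mixtures of photons and neutrons whose proportions
differ from person to person. `mixdose` implements an integrated analysis
of radiation-responsive biomarkers measured in blood and urine (qRT-PCR
transcript C_T values, serum and urine metabolite intensities,
flow-cytometry blood cell counts) that:

1. estimates a **biomarker-weighted neutron relative biological
   effectiveness (RBE)** and the resulting **photon-equivalent dose**

   D_PE(RBE) = D_P + RBE · D_N

   RBE_opt = argmax_RBE Σ_i cor(D_PE(RBE), S_i)²

   where D_P and D_N are the photon and neutron doses and S_i the signal of
   biomarker *i* — every biomarker votes through its squared Pearson
   correlation, whether it rises or falls with dose;
2. engineers the analysis features: the seven-gene **net signal**
   (difference of geometric means of the C_T-down and C_T-up gene groups),
   ln-transformed cell counts, the ln neutrophil/lymphocyte ratio, and
   random within-stratum matching of blood-count donor animals;
3. screens predictors by correlation with D_PE (|r| ≥ 0.3) and
   multicollinearity (|r| ≥ 0.7 with several other predictors);
4. selects all-relevant biomarkers by a **shadow-feature (Boruta-style)
   procedure**: per-iteration re-randomized shadow copies compete with real
   features inside a random forest, hits above the 50th shadow percentile
   are tested against a Binomial(0.5) null at α = 0.05 with Bonferroni
   correction;
5. reconstructs four dosimetry endpoints (photon-equivalent dose and
   neutron dose as regressions; neutron fraction ≥ 10% and neutron dose
   ≥ 0.5 Gy as classifications) and a biological-injury endpoint (ln CD19
   cell counts) with **stacked ensembles**: level0 learners fitted by
   repeated five-fold cross-validation (10 repeats), their out-of-fold
   predictions feeding a level1 meta-model (random forest for regression,
   gradient-boosted trees for classification);
6. evaluates with RMSE/MAE/R², ROC AUC with a **10,000-replicate bootstrap
   CI**, balanced accuracy, sensitivity/specificity, confusion matrices and
   per-exposure-group error tables.

A synthetic cohort generator reproduces the statistical structure of the
motivating mouse study design — 89 animals in six groups (sham, plus 3 Gy
total at neutron fractions 0/10/20/30/80%, i.e. neutron doses 0/0.3/0.6/
0.9/2.4 Gy), sampled 1 and 7 days after exposure, both sexes, per-biomarker
linear dose response with biomarker-specific RBE — so the entire pipeline
is developed and tested without access to animal data.

## Worked example

```r
library(mixdose)

panel <- generateCohort(defaultDesign(), defaultBiomarkerSpecs(), seed = 1)
panel
#> BiomarkerPanel: 89 samples x 40 biomarkers
#>   categories: blood_count=4, gene=7, metabolite_serum=17, metabolite_urine=12
#>   groups: sham, 3Gy_0pctN, 3Gy_10pctN, 3Gy_20pctN, 3Gy_30pctN, 3Gy_80pctN

res <- runPipeline(runConfig(seed = 1))
res$rbeFit
#> RbeFit: RBE_opt = 1.338 over 40 biomarkers, 45 samples
#>   objective at optimum: 13.71

res$reports$photon_equivalent_dose
#> EvalReport (regression):
#>    rmse               0.2413
#>    mae                0.1681
#>    r_squared          0.9675

res$reports$neutron_10_percent
#> EvalReport (classification):
#>    auc                0.8304
#>    balanced_accuracy  0.8393
#>    accuracy           0.8636
#>    sensitivity        0.9286
#>    specificity        0.75
#>    AUC 95% CI: (0.6585, 0.9688) from 10000 bootstraps

res$reports$neutron_10_percent@subgroupErrors
#>        group n n_misclassified
#> 1  3Gy_0pctN 7               4
#> 2 3Gy_10pctN 8               0
#> 3 3Gy_20pctN 6               1
#> 4 3Gy_30pctN 8               1
#> 5 3Gy_80pctN 6               0
#> 6       sham 9               0
```

Reading these numbers: the neutron RBE fitted on the 45-animal training
half is ≈ 1.34, so the five exposed groups sit at photon-equivalent doses
between 3 and ~3.8 Gy — close together, which is why D_PE itself is
reconstructed very well (R² ≈ 0.97, RMSE ≈ 0.24 Gy: mostly the easy
sham-vs-exposed contrast) while the numeric neutron dose is not
(`res$reports$neutron_dose` has R² ≈ 0.07). Detecting *whether* ≥ 10% of
the exposure was neutrons works well (AUC ≈ 0.83), and the subgroup table
shows the residual difficulty is concentrated exactly where expected: the
3 Gy photon-only animals are the ones mistaken for neutron-exposed. The
CD19 injury endpoint (`res$reports$cd19_outcome`) reaches R² ≈ 0.75 from
genes and metabolites alone. The ablation `runConfig(seed, mode =
"no-cd19")` repeats the dosimetry endpoints without CD19 counts, and
`mode = "cd19-outcome"` runs only the injury endpoint.

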