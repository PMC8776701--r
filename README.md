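# rpvent

Ventilation-weighted dose features and radiation-pneumonitis (RP) prediction
from 4D-CT.

## The problem

Thoracic radiotherapy trades tumor control against inflammatory lung toxicity
(radiation pneumonitis, CTCAE grade >= 2). Conventional predictors summarize
the planned dose over the anatomical lung — the dose-volume histogram (DVH) —
under the assumption that lung function is spatially homogeneous. It is not:
respiration-resolved CT (4D-CT) plus deformable image registration (DIR)
yields a voxelwise ventilation image, and weighting the dose distribution by
that regional function (the dose-function histogram, DFH) asks the sharper
question of how much dose the *working* lung receives.

`rpvent` implements that analysis end to end for researchers in radiotherapy
outcome modelling:

1. **Ventilation imaging.** From a registered peak-inhale/peak-exhale CT pair
   and the DIR displacement field `u(x)` (exhale grid, pointing into the
   inhale image), two standard metrics of specific volume change:
   - HU metric: `V_HU = (HU_ex − HU_in{x+u}) / (HU_in{x+u} + 1000)`,
     from the air/tissue mixture model of CT intensity;
   - Jacobian metric: `V_Jac = det(I + ∇u) − 1`,
     by central finite differences of the field.
   Ventilation is converted per patient to a rank-percentile function map.
2. **Dose features.** Physical dose is converted voxelwise to the equivalent
   dose in 2-Gy fractions, `EQD2 = D (d + α/β)/(2 + α/β)` with
   `d = D/n_fractions` and `α/β = 3` Gy, then reduced over the healthy lung
   (lungs minus GITV minus trimmed airways/vessels) to MLD and V5–V50
   (percent volume exceeding x Gy), and their function-weighted analogues
   fMLD and fV5–fV50 using the percentile map as voxel weight. Clinical
   geometry (normalized GITV position, GITV volume) completes the panel.
3. **Modeling protocol.** Four nested candidate sets — (i) clinical,
   (ii) + DVH, (iii) + DFH, (iv) + DVH + DFH — are evaluated with repeated
   stratified 70/30 splits (50 models by default). Per split, features are
   z-scored on the training partition only and an RBF-kernel SVM is tuned
   (`C`, `γ`) by Bayesian optimization through stratified 5-fold inner CV;
   AUC is computed from decision scores on both partitions. Feature sets are
   compared with paired Wilcoxon signed-rank tests; per-feature screens use
   Mann-Whitney U; feature redundancy uses Spearman correlation.
4. **Phantom cohort.** Patient data of this kind are rarely shareable, so the
   package ships a parametric phantom generator: ellipsoidal lungs, smooth
   displacement fields with closed-form Jacobians (linear/radial/sinusoidal
   families), CT pairs constructed to encode a known ground-truth
   ventilation, Gaussian dose falloff around a spherical GITV, and binary RP
   labels from a stated logistic model on the computed features with
   auto-calibrated incidence. Every stage of the pipeline is testable
   against analytic oracles.

## Worked example

```r
library(rpvent)

# one synthetic patient: masks, field, CT pair, dose; then its features
p  <- make_phantom_patient(phantom_spec(seed = 17))
round(patient_features(p, metric = "hu")[c("MLD","V5","V20","fMLD","fV5","fV20")], 2)
#>   MLD    V5   V20  fMLD   fV5  fV20
#>  8.35 33.55 15.72 11.26 41.88 21.71

# a 60-patient cohort whose RP labels load on fV20 (2 SD units, logistic)
co <- make_cohort(cohort_spec(n_patients = 60, seed = 42))
co$table
#> <feature_table> 60 patients x 20 features, 12/60 RP-positive (20.0%)

ex <- run_experiment(co$table, scheme = split_scheme(n_repeats = 20, seed = 1))
ex
#> <rp_experiment> 20 repeats x 4 feature sets (70/30 split)
#>               set median_test_auc iqr_test_auc median_train_auc
#>          clinical           0.679        0.147            0.903
#>      clinical_dvh           0.848        0.134            0.993
#>      clinical_dfh           0.857        0.116            0.917
#>  clinical_dvh_dfh           0.893        0.112            0.939

compare_feature_sets(ex$runs[ex$runs$set == "clinical_dvh_dfh", ],
                     ex$runs[ex$runs$set == "clinical", ])
#> [1] 0.000142
```

Read: the mean EQD2 over the healthy lung of this phantom is 8.35 Gy, 15.7%
of it receives more than 20 Gy, and the function-weighted fV20 (21.7%) is
higher — the high-ventilation region sits in the dose bath. Across the
cohort, feature sets that include the DFH features recover the injected
fV20 effect (median test AUC 0.86–0.89 versus 0.68 for clinical features
alone; paired Wilcoxon p = 1.4e-4), while the train/test AUC gap shows the
inner-CV tuning keeping overfitting in check. `summary(ex)` adds quartile
deviations, percentile and normal-theory 95% intervals, and the full
pairwise p-value matrix; `plot(ex)` draws the per-set AUC boxplots.

`run_pipeline(run_config(...), out_dir)` executes the whole chain —
simulate, ventilate, extract, model, report — for the HU and/or Jacobian
metric and writes feature/run/summary/correlation CSVs plus a manifest with
content hashes; reruns with the same configuration are byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main end-to-end analysis from scratch: it simulates
a seeded 40-patient phantom cohort, runs the repeated-split SVM experiment
for both ventilation metrics with shared splits, prints the per-metric
summaries, and writes the results JSON to `--out`.
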