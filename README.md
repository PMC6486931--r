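# mpcad

Computer-aided segmentation and diagnosis of breast lesions from
co-registered multiparametric PET/MRI.

Breast lesions show characteristic signatures across imaging modalities:
malignant tissue enhances rapidly after contrast injection and then washes
out (DCE-MRI), restricts water diffusion (low ADC on DWI) and takes up more
FDG (PET). `mpcad` implements a two-stage machine-learning pipeline over
such data:

1. **Voxel-wise lesion segmentation.** Every voxel inside the breast mask is
   described by a 62-dimensional intensity feature vector — 26 consecutive
   DCE frames from the enhancement onset, 25 time-normalised two-frame
   forward differences, the normalised summed enhancement, pre/peak/post
   high-resolution intensities and their pairwise differences, DWI b0/b850,
   ADC and PET — and classified lesion/background by a random forest trained
   on 1000 sampled voxels per class per patient. The probability threshold
   maximises training-set Dice; predictions are cleaned by 6-connected
   component post-processing.

2. **Lesion-level benign/malignant classification.** Each lesion contributes
   143 features: its *characteristic kinetic curve* (the fuzzy-c-means
   cluster-centre curve with the highest enhancement rate, 25 points and 21
   four-frame differences), the parameters of the kinetic regression model

   C(t) = G · (1 − [1 + (2^α − 1) · exp((t − t½)/τ)]^(−1/α)) · exp(β·t^k)

   (an asymmetric generalised logistic wash-in times an exponential washout
   term) with its 7-minute summaries AuC, Cmax, Tmax, T½ and the maximum
   analytic derivative; six 13-statistic Haralick blocks from 128-bin
   grey-level co-occurrence matrices — spatial texture over the 26-neighbour
   3-D neighbourhood on the pre/peak/post volumes, and spatio-temporal
   texture pairing each voxel with itself across the (pre,peak), (pre,post)
   and (peak,post) time points; the lowest-ADC and highest-PET five-cluster
   centres; and eight shape descriptors. A random forest with an
   F1-maximising threshold separates the classes.

Feature contribution is quantified with Gini importance and
minimum-redundancy-maximum-relevance (mRMR) rankings, incremental top-k
performance curves and modality ablations (without DWI and/or PET), all
evaluated by leave-one-out cross-validation with in-fold ranking (no
leakage) and repeated runs.

Because clinical studies are not shipped, the package includes a seeded
synthetic phantom generator (`make_cohort()`) that emulates the study
conditions — class-specific enhancement kinetics, reduced ADC and elevated
PET uptake in malignant lesions, enhancing vessel-like distractors, additive
noise — and provides ground truth for every stage.

## Worked example

```r
library(mpcad)

cohort <- make_cohort(phantom_config(n_patients = 6, seed = 1))
cohort
#> Synthetic multiparametric cohort: 6 studies
#>   lesions: 6 (3 malignant, 3 benign)
#>   grid 40x40x24, 34 DCE frames

loocv_segmentation(cohort, seg_config(seed = 1))
#> LOOCV segmentation evaluation
#>   mean_dsc_lesion median_dsc_lesion  mean_dsc_patient  mean_sensitivity
#>                 1                 1                 1                 1
#>    detection_rate
#>                 1

tab <- cohort_lesion_table(cohort, seed = 1)
loocv_classification(tab, cls_config(repeats = 5, seed = 1))
#> LOOCV classification: AUC 1.000 +/- 0.000; sens 1.000, spec 0.867 (5 repeats)
```

The mean lesion Dice of 1 and AUC of 1 say that on this high-contrast,
noise-lite phantom cohort every lesion voxel is recovered and every lesion
class is ranked correctly; the specificity below 1 reflects the conservative
F1 threshold chosen inside the small training folds. Fitting the kinetic
model to the first study's characteristic kinetic curve:

```r
s <- cohort[[1]]$study
ckc <- characteristic_kinetic_curve(s$dce, s$annotation == 1,
                                    s$enhancement_onset, s$times, seed = 1)
fit_kinetic(ckc)
#> Kinetic fit (sigmoid x exponential)
#>        G    alpha      tau   t_half     beta        k
#>  3.29754  1.42848 21.11102 89.07832 -0.00010  1.26766
#> RSS 0.002211; converged: TRUE
#> Summaries (7-min window):
#>        auc       cmax       tmax t_half_obs       mder
#>   971.2506     2.9948   204.6173    85.8783     0.0331
```

This lesion is malignant: it reaches half-maximum enhancement early
(`t_half_obs` ≈ 86 s) and peaks inside the 7-minute window (washout).
Benign phantom lesions fit with `t_half` beyond 160 s and peak at the window
end.

A thin command-line front end over the same functions is installed at
`inst/cli/mpcad.R` (`simulate`, `mask`, `features`, `segment`, `classify`,
`rank` subcommands).

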