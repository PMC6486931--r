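---
title: "Multiparametric PET/MRI CAD for breast lesions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric PET/MRI CAD for breast lesions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mpcad` is a two-stage computer-aided segmentation and diagnosis pipeline
for co-registered multiparametric breast imaging: DCE-MRI (a 4-D time
series), high-resolution pre/peak/post contrast volumes, DWI (b0, b850, ADC)
and FDG-PET, all on one voxel grid. This vignette explains the models the
package implements, the tunable parameters that matter, what the synthetic
phantom does and does not emulate, and the numerical and design choices made
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The data model

An `mp_study` holds one patient's volumes plus per-frame acquisition times,
the enhancement-onset frame index `j`, a binary breast mask and a lesion
label volume with benign/malignant labels. Validity checks enforce the
co-registration contract (one grid for all volumes), strictly increasing
times, a 26-frame DCE window from `j`, and that every annotated voxel lies
inside the breast mask. Indices are 1-based and arrays follow the
`(x, y, z[, frame])` axis order of the NIfTI I/O layer (`RNifti`).

Intensity standardisation maps each MRI volume affinely to zero mean and
unit SD estimated over the breast mask. For the 4-D series the statistics
come from the pre-contrast frames only (frames before `j`) and the *same*
affine map is applied to every frame, so inter-frame contrast — the signal
the kinetic features live on — is preserved. DWI and PET are consumed raw:
whether they should be standardised is left open by the design this package
follows, and their features are either ratio-free (cluster centres) or used
by scale-insensitive tree ensembles. One bookkeeping consequence: the
normalised summed enhancement `f_nsumdce` is computed on the *raw* DCE
signal (clamped at zero) and divided by its in-mask maximum, because sums of
zero-mean standardised intensities would be negative and the feature is
specified to lie in [0, 1] with in-mask maximum 1.

The breast mask is grown by intensity-based region growing: Otsu's threshold
on the pre-contrast histogram, then the largest above-threshold 6-connected
component. This is deliberately parameter-light; clinical data with skin
folds or coil artefacts may need a manual mask, and `read_study()` accepts
one.

## Voxel features and segmentation

Each in-mask voxel contributes 62 features: 26 DCE frame intensities from
`j`; 25 forward differences `(I(x, i+2) − I(x, i)) / (t_{i+2} − t_i)`; the
normalised summed enhancement; three high-resolution intensities and their
three pairwise differences; DWI b0/b850 and ADC; and PET. The difference
window starts at `i = j` and needs frames up to `j + 26`; when the series is
exactly one frame short the window start moves back one frame. This
convention (25 differences, not 26) is a documented choice: the feature
count and the index range printed for this feature set are mutually
inconsistent, and we match the count with the smallest frame demand.

Enhancement onset is detected as the first frame whose mean in-mask signal
exceeds the mean of all earlier frame means by more than twice their SD (at
least two baseline frames). On noise-free phantoms this recovers the
generator's onset frame exactly; with noise it can land a frame late, which
only shifts the feature window.

Segmentation is voxel-wise classification: a random forest (100 trees,
default Gini splits, seeded) trained on up to 1000 voxels per class per
patient, sampled without replacement. The probability threshold is chosen on
a grid of 101 values in [0, 1] to maximise the mean training-set Dice
coefficient, ties broken toward the smallest threshold (favouring
sensitivity). Post-processing labels 6-connected components; in evaluation
mode, components that do not touch the annotation are removed — the
automated analogue of a radiologist picking the suspicious blob. Dice of two
empty masks is defined as 0. Evaluation is leave-one-out over patients; DSC
is reported per lesion (blobs touching that lesion against its mask) and per
patient, and a lesion counts as detected when at least one predicted blob
overlaps it.

## Lesion features

**Characteristic kinetic curve (CKC).** In-lesion relative-enhancement
curves (raw signal minus the voxel's pre-onset baseline mean) over the 25
frames from `j` are clustered by fuzzy c-means; the cluster-centre curve
with the highest enhancement rate, `(max(curve) − curve[1]) / (t_max − t_1)`,
is the CKC. The cluster count (5) and fuzziness (m = 2) are conventional FCM
settings, matching the five clusters used for the ADC/PET features; the rate
criterion is a literal reading of "highest contrast enhancement rate" and is
isolated in one small function should a different criterion be preferred.
Lesions smaller than the cluster count, or with fewer distinct curves than
clusters, fall back to the mean curve with a warning. The FCM itself is a
native implementation — alternating membership/centre updates to a 1e-9
membership tolerance with seeded initial centres drawn from distinct data
rows — because bit-identical reproducibility under a fixed seed is part of
the package's contracts; it agrees with `e1071::cmeans` to clustering
accuracy (a cross-check test asserts this).

**Kinetic model.** The CKC is fitted with bounded Levenberg–Marquardt least
squares (three seeded starts) to

$$C(t) = G\,\Big(1 - \big[1 + (2^{\alpha}-1)\,
e^{(t - t_{1/2})/\tau}\big]^{-1/\alpha}\Big)\, e^{\beta t^{k}},$$

where `G` scales the curve, `alpha` sets the asymmetry, `tau` the steepness
and `t_half` the sigmoid's half-maximum time; `beta < 0` with exponent `k`
produces washout. Time is measured from contrast arrival, placed one frame
interval before the first enhancing frame, so the first sample sits at
`t > 0` and `t^k` is well defined for `k < 1`. The parameters `alpha, tau,
beta, k` are features; `G` and `t_half` enter indirectly through the curve
summaries over the 7-minute window: trapezoidal AuC on a dense grid, Cmax
and Tmax by grid search plus local refinement, T½ as the earliest
half-maximum crossing (bisection), and MDER as the maximum of the *analytic*
derivative of `C`. Identifiability caveat: when `beta = 0` the exponential
term vanishes and `k` is meaningless; the phantom priors therefore keep
`beta` strictly negative for both classes (benign only barely so). Fits that
fail to converge are flagged, not zeroed, and downstream consumers impute
flagged values by training-fold medians.

**Texture.** Spatial texture quantises in-mask intensities into 128
equal-width bins over the in-mask range and accumulates co-occurrences over
all 26 unit offsets with both voxels in-mask, symmetrised and normalised;
13 second-order (Haralick) statistics are computed per matrix (energy,
contrast, correlation, variance, homogeneity, sum average/variance/entropy,
entropy, difference variance/entropy, and the two information measures of
correlation; natural logs, 0·log 0 := 0, correlation-type statistics
defined as 0 under degenerate marginals). Binning over the in-mask range
makes the statistics invariant to affine intensity rescaling, so whether the
input volume was standardised is immaterial away from binning edge cases.
Spatio-temporal texture pairs each voxel's quantised intensity with itself
at a later time point — (pre,peak), (pre,post), (peak,post) — with both
volumes sharing bins over their pooled range; its energy measures how
uniformly the lesion enhances over time. The sum-variance statistic is
centred on the sum average (the common modern convention) rather than the
sum entropy.

**ADC/PET cluster extremes and shape.** In-mask ADC and PET intensities are
partitioned into five fuzzy clusters; the lowest ADC centre and highest PET
centre are the features (minimum/maximum with a flag when fewer than five
voxels or distinct values exist). Shape descriptors are spacing-aware:
volume; surface area as the integral of the gradient magnitude of the
Gaussian-smoothed indicator (smoothing scale 0.8 of the smallest voxel edge
— on digital balls of radius 3–10 voxels this estimator is within ~3% of the
analytic surface, where naive face counting errs by ~50%); compactness
`36πV²/S³` and sphericity; mean/SD of surface-voxel-to-centroid radii;
elongation as the ratio of extreme principal-axis SDs; and convexity
`V/V_hull` with the hull volume approximated slice-wise by 2-D convex hulls
— the whole set is approximate by design and labelled so.

The assembled lesion vector has 143 named entries carrying modality group
tags (DCE ×133, DWI ×1, PET ×1, MORPH ×8) so ablations and group-level
rankings need no name parsing.

## Classification, ranking and evaluation

The lesion classifier is a seeded 100-tree random forest. Its decision
threshold maximises the training-set F1 score over the same 101-point grid
(smallest-tie rule) — computed on the forest's *out-of-bag* votes: in-bag RF
probabilities are overfit to near 0/1, which would drag the smallest tied
threshold to the bottom of the grid and destroy held-out specificity. OOB
votes are still strictly within the training set.

Gini importance is the forest's mean impurity decrease, normalised to sum 1;
redundant informative features are co-ranked highly. mRMR uses the MID
(difference) form on equal-frequency 3-bin discretised features: the first
pick maximises mutual information with the label, each next pick maximises
relevance minus mean redundancy to the selected set; ties break to the
earlier column. The variant and discretisation are the original defaults for
continuous data; the contrast the two rankers are expected to show — mRMR
demotes an exact duplicate below a weaker independent feature, Gini co-ranks
the duplicates — is asserted by tests on seeded simulations.

LOOCV treats the lesion as the unit (multifocal patients contribute several
lesions); ranking and threshold selection are recomputed inside every
training fold, so permuting a held-out label cannot change its fold's model
(a test asserts this). Experiments repeat 20 times by default, varying only
seeds; AUC (rank-based, midrank ties — equal to Mann–Whitney) is reported as
mean ± SD, sensitivity/specificity as means of per-repeat confusions.
`classify_from_segmentation()` re-extracts lesion features from predicted,
post-processed blobs, falling back to the manual annotation (flagged) for
undetected lesions, so classification can be compared between manual and
automatic delineations.

## The phantom: what it emulates, and what it does not

Each phantom study places spherical lesions (radius 6–12 mm, one per
patient by default, 2/3 malignant) inside an ellipsoidal breast on a
40×40×24 grid of 2 mm voxels, with a 34-frame DCE series at 13.2 s per
frame and contrast arriving at frame 7 — so the 26-frame feature window
always exists. Lesion enhancement follows the kinetic model with
class-specific priors chosen for separability (the design leaves clinical
parameter values unstated): malignant `G ∈ [1.8, 2.6]`, `tau ∈ [10, 25] s`,
`t_half ∈ [50, 90] s`, `beta ∈ [−7, −3]·10⁻⁴` (fast wash-in, washout);
benign `G ∈ [0.8, 1.4]`, `tau ∈ [40, 70] s`, `t_half ∈ [160, 240] s`,
`beta ∈ [−1.5, −0.5]·10⁻⁴` (slow, persistent). A multiplicative per-voxel
enhancement-scale field (SD 0.25 malignant, 0.08 benign) gives malignant
lesions a more heterogeneous texture. ADC is 0.9/1.6/2.0 ×10⁻³ mm²/s for
malignant/benign/background and DWI follows the mono-exponential forward
model `S(b) = S0·exp(−b·ADC)`; PET uptake is 5/2/1. A smooth random
"fibroglandular" field textures the pre-contrast anatomy (without it the
noise-free breast would have zero variance and standardisation would be
undefined). Vessel-like tubes (default 2) enhance with fast vascular
kinetics but keep background ADC/PET and are excluded from the annotation —
they exist so false-positive removal is exercised. Peak/post high-resolution
volumes are rendered from the same kinetic model at the cohort's median Tmax
and at end-of-acquisition. Additive Gaussian noise (default 5% of each
modality's tissue scale) is applied last. Cohorts are pure functions of
(config, seed).

Not emulated: registration misalignment, breast-compression deformation,
PET partial-volume effects, bias fields, enhancing parenchyma beyond the
tubes, non-spherical lesion morphology. Consequently the passing end-to-end
tests demonstrate that the pipeline's machinery is correct and its
contracts hold on separable data; they do not certify clinical segmentation
or classification accuracy, which in real cohorts is dominated by exactly
the confounds the phantom omits (low-enhancing lesions, parenchymal uptake,
alignment error).

## Problem sizes, determinism and limitations

The shipped experiments use sizes chosen to keep the full suite comfortably
reproducible on a single CPU: an 8-study cohort for segmentation LOOCV, a
30-lesion cohort (20 repeats) for classification, 100 curves for kinetic
parameter recovery, and ≤5×5×5 volumes for the exhaustive co-occurrence
oracles. All randomness flows through explicit integer seeds; child seeds
are derived arithmetically and kept within 32-bit range. Known limitations:
the region-growing mask and onset detector are deliberately simple; the
convex-hull volume is a slice-wise approximation; the shape set is a
standard literature set rather than a canonical reference list; and mRMR's
discretisation (3 bins) trades MI estimation bias for variance at the
cohort sizes used here.
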