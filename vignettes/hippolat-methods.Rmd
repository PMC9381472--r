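---
title: "Quantitative PET/T2 lateralization of temporal lobe epilepsy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET/T2 lateralization of temporal lobe epilepsy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippolat)
```

## The problem

In mesial temporal lobe epilepsy (MTLE), surgical planning hinges on
*lateralization*: deciding whether the epileptogenic hippocampus is on the
left or the right. In patients whose structural MRI looks normal
("MR-negative"), visual reads of FLAIR and even FDG PET often fail, and the
question becomes quantitative: do subtle hippocampal signal changes —
T2 prolongation from gliosis, glucose hypometabolism — carry enough
left/right asymmetry to call the side?

`hippolat` implements that quantitative pipeline end to end:

1. voxel-wise T2 relaxometry from a multi-echo spin-echo series, with a
   CSF exclusion rule;
2. PET intensity normalisation to SUVR by global-mean scaling;
3. normative voxel-wise z-score maps against a healthy-control cohort,
   after FWHM-specified Gaussian smoothing;
4. eroded hippocampal ROI extraction and left-minus-right asymmetry
   indices (AIs);
5. leave-one-out cross-validated (LOOCV) logistic lateralization with
   ROC/AUC, probability mean squared error, and accuracy summaries;
6. nonparametric paired and two-sample group comparisons.

Because clinical images cannot be redistributed, the package ships a
synthetic-data module that generates both image-level phantoms and
cohort-level feature tables with the published group statistics of a 3T
hybrid PET/MR MTLE cohort (24/15 controls and 12/14/10/10 patients across
the four MR-visibility x side subgroups, see `default_group_params()`).

## Models and estimators

### T2 relaxometry

Each voxel's multi-echo signal is modelled as a monoexponential decay
$S(TE) = S_0 e^{-TE/T_2}$ sampled at six echo times (10.5–63.0 ms in
10.5 ms steps). The default estimator is weighted log-linear least squares:
regressing $\ln S$ on $TE$ with weights proportional to $S^2$, which is the
first-order maximum-likelihood weighting under additive Gaussian noise and
is exact in the noiseless limit. A bounded nonlinear refinement
(`refine = TRUE`, L-BFGS-B on the signal-domain sum of squares) is
available; on noiseless input the two agree to well under 0.1 ms. Voxels
with any non-positive echo signal or a non-negative decay slope are marked
invalid rather than partially fit, and fitted values are clipped at
5000 ms before thresholding so near-flat decays cannot overflow.

Noise propagation is governed by the Fisher information of the six-echo
design: at $T_2 = 110$ ms and 2% relative noise the Cramér–Rao bound gives
a per-voxel SD of about 7.7 ms. Per-voxel tests therefore check the
information-bound scale, while ROI-averaged quantities (the pipeline's
actual currency) are accurate to well under 1 ms at that noise level.

Voxels with fitted $T_2 > 170$ ms are excluded as CSF-contaminated
(`apply_csf_threshold()`); the comparison is strict, so exactly 170 ms is
retained, and the rule is idempotent.

### SUVR

PET uptake is divided by its mean over the whole-brain mask
(`compute_suvr()`), which cancels injected dose and scanner scaling; the
in-mask mean of the result is exactly 1 and the map is invariant under any
positive rescaling of the input. The reference region is the whole brain
mask by default and is exposed as a parameter; injected dose and body
weight are deliberately not modelled, since the ratio cancels them.

### Normative z-scoring

Maps are smoothed with a separable isotropic Gaussian specified by its
FWHM (4 mm for T2, 8 mm for SUVR by default;
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, converted to voxel units per
axis). Invalid voxels are handled by normalised (mask-weighted)
convolution: the masked values and the mask are convolved with the same
kernel and divided, so invalid voxels neither leak values nor become
valid, and constant maps are preserved exactly. Smoothing happens *before*
z-scoring for controls and patients alike; the pipeline enforces that
ordering.

The normative model takes the per-voxel sample mean and SD (n−1) over the
smoothed control maps; a voxel is valid only where every control is valid.
Patient z-maps are $(x - \mu_{HC})/\sigma_{HC}$; voxels whose control SD
falls below `1e-6` (modality units) are invalid, since degenerate control
variance carries no normative information. Z-scoring each control against
the full-cohort model returns per-voxel mean 0 and SD 1 to within 1e-10 —
a self-normalisation identity the tests assert.

The spatial-normalisation step of a clinical pipeline (registration to a
template and back) is out of scope here: synthetic subjects are generated
already co-registered on a shared grid, so the inverse-warp step is a
documented no-op.

### ROI extraction and asymmetry indices

Hippocampal label masks are eroded with one pass of a 6-connected
3-D cross structuring element ("standard" morphological erosion; the
element and single pass are a deliberate minimal choice) to reduce
partial-volume contamination at the CSF border; if erosion would empty a
mask the un-eroded mask is used and a warning recorded. ROI means use only
valid voxels, so CSF-excluded T2 voxels drop out.

The hippocampal z value of a subject is the **mean of voxel-wise z within
the eroded ROI** (rather than the z of the ROI mean; the two readings are
both defensible and the alternative is one line of user code, since
`extract_roi_mean()` accepts any map). The asymmetry index is left minus
right of those z means, per modality. Raw left-minus-right differences and
their laterality-oriented (ipsilateral-minus-contralateral) counterparts
are carried per subject; for left-sided disease the two coincide, for
right-sided disease the sign flips, exactly.

The "normal range" of an AI is the central 95% empirical percentile
interval of the control AI distribution (`control_reference_interval()`);
a normal-theory mean ± 1.96 SD variant is offered as an option. The
empirical reading was chosen because control cohorts of 15–24 subjects are
too small to defend normality and percentiles are what the downstream
"within normal variation" flag needs.

### Lateralization

Left-sided disease is the positive class. The classifier is binary
logistic regression fit by penalized maximum likelihood with an L2 ridge
on the slope coefficients (intercept unpenalized); the default strength
`penalty_c = 1` follows the inverse convention (larger = weaker) of the
widely used scikit-learn default, and is needed because at n = 24 with
near-separable features the unpenalized likelihood diverges. An
unpenalized ML option (`penalized = FALSE`) delegates to `stats::glm`.
Features enter as-is (AIs are already z-derived); standardisation is
available as a flag. The implementation is a dozen-line Newton iteration
whose held-out probabilities were cross-checked against the reference
scikit-learn implementation to ~1e-4 during development.

LOOCV refits the model n times, records each held-out subject's
probability, and pools the n held-out probabilities into a single ROC.
The AUC is the Mann–Whitney probability that a random positive outranks a
random negative (ties one-half), identical to the trapezoidal area under
the empirical ROC and — a cross-module identity the tests exploit — to
$U/(n_a n_b)$ of the rank-sum test. Hard side calls use a 0.5 threshold;
an exact tie is "undetermined" and counts as incorrect. The probability
MSE is the mean of (label − probability)².

### Group statistics

Paired left-vs-right comparisons use the Wilcoxon signed-rank test (zero
differences dropped, the classical convention; Pratt's method is an
option), two-sided, exact by complete enumeration of the null when at most
12 tie-free differences remain, otherwise a continuity- and tie-corrected
normal approximation. Independent group comparisons use the two-sided
Mann–Whitney U test with the same exact/approximate policy. Alpha is 0.05
two-sided and no multiplicity correction is applied, matching the
analysis protocol the package reproduces.

## The synthetic-data generator

The generator is the package's study population, not a test fixture, and
its defaults are the study conditions.

**Feature level.** `generate_cohort_features()` draws per-subject AIs from
normal distributions with the published group moments (e.g. MR-negative
left MTLE: AI\_T2 ~ N(0.38, 0.81²), AI\_SUVR ~ N(−0.61, 0.65²)). The two
AIs are independent by default because their within-subject correlation is
not published; the correlation is exposed (`ai_correlation`) so its effect
can be explored.

**Image level.** `generate_phantom_subject()` renders a 64 × 64 × 32 grid
at 2 mm isotropic (desk-scale: seconds per subject): a brain ellipsoid
with background tissue at T2 = 90 ms, a midline CSF compartment at
2000 ms (the two straddle the 170 ms rule), and two disjoint hippocampal
ellipsoids carrying the requested per-subject T2 and SUVR. Echo images are
$S_0 e^{-TE_k/T_2}$ plus additive Gaussian noise of SD
`noise_sd_relative * S0` (2% default, i.e. SNR 50 at the first echo);
$S_0 = 1000$ inside the brain, 0 outside. PET uptake levels are solved
exactly so that noiseless global-mean scaling returns the requested
hippocampal and CSF SUVRs, then multiplied by a random per-subject dose
factor that the SUVR step must cancel. Left/right raw values are drawn as
bivariate normals with correlation 0.5 (unpublished; exposed as
`lr_correlation`), which keeps the SD of left-minus-right differences near
their reported per-subject values. The convention throughout is left
hemisphere at lower first-axis indices; NIfTI orientation metadata is
honoured on reading real files.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: acquisition physics (stimulated echoes, TR
effects, multi-compartment relaxation), Rician noise statistics (additive
Gaussian is adequate at SNR ≥ 20 but wrong near zero signal), partial
volume at tissue interfaces, motion, registration error, segmentation
error, and attenuation-correction artifacts. Hippocampi are ellipsoids,
not hippocampi.

## Numerical choices

* T2 fits: invalid on any non-positive echo; 5000 ms clip; all six echoes
  used by default (dropping the first echo, common practice against
  stimulated-echo bias, is available in `fit_monoexponential` inputs by
  simply subsetting).
* Smoothing kernels truncate at 4σ; any kernel normalisation cancels in
  the mask-weighted division.
* z-maps: control-SD floor 1e-6.
* Ridge logistic: Newton iteration to gradient norm 1e-10, Hessian
  weights floored at 1e-10.
* Reference intervals: type-7 quantiles; `level = 1` returns the range.
* Erosion to an empty mask warns and falls back to the un-eroded mask.

## Problem sizes used in the checks

The replicate study behind the headline AUC figures simulates 200 cohorts
of 24 MR-negative patients (14 left, 10 right) and runs all three LOOCV
models on each. Image-level tests use a 32 × 32 × 16 phantom grid, and the
end-to-end pipeline test runs the full default cohort (85 subjects) on
that grid; these sizes were chosen so the whole suite runs in a few
minutes on a laptop while keeping every cohort-level quantity at its
study-condition value.

## Known limitations and observed behaviour

* The mean LOOCV AUC of the pooled-probability ROC is a *pessimistically
  biased* estimate of a model's population AUC at n = 24: fold-specific
  intercept shifts scramble the pooled ranks. In the replicate study this
  costs roughly 0.03–0.05 AUC relative to the closed-form population
  values (Φ-transformed Mahalanobis separations of the generating
  Gaussians). The combined T2+PET model dominates each single modality at
  the set level, as expected; the univariate T2 replicate mean
  (~0.79) sits below its single-cohort published counterpart (0.843) by
  slightly more than the nominal band, which is consistent with that bias
  plus the unpublished feature correlation. The acceptance suite reports
  the honest simulated values.
* The per-voxel T2 error at 2% noise is information-bound (~7.7 ms SD),
  so claims of millisecond-level per-voxel accuracy at that SNR are not
  attainable by any estimator; ROI averages are.
* Wilcoxon exact vs normal-approximation p values can differ by up to
  ~0.017 at n = 10–12; the tests assert the typical (median) agreement at
  the percentage-point level.
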