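---
title: "Dynamic radiomics of 4D perfusion MRI: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic radiomics of 4D perfusion MRI: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Dynamic susceptibility contrast perfusion-weighted MRI (DSC-PWI) records a
4D signal `S(x, y, z, t)`: as a gadolinium bolus transits brain tissue, the
signal drops transiently and recovers. In ischemic stroke, both the lesion
and the rest of the brain carry information about the patient's functional
recovery (90-day modified Rankin Scale, dichotomized into good/poor).
`dynrad` implements a *dynamic radiomics* analysis of such data: radiomics
features are extracted from every 3D timepoint within a region of interest,
indexed by their position in the time series ("dynamic radiomics features",
DRFs), screened statistically, condensed by a Lasso cascade into four
feature groups — whole-brain (`Lasso(WB)`), lesion (`Lasso(LL)`), their
concatenation (`combined`), and a second Lasso pass on the concatenation
(`Lasso(combined)`) — and compared across ten classifiers by stratified
cross-validated AUC.

Because clinical DSC-PWI datasets of this kind are not publicly
distributable, the package includes a first-class synthetic cohort
generator whose statistical structure matches what the analysis assumes.
Every downstream stage is therefore testable end to end.

# The synthetic cohort model

Each voxel follows an exponential signal-attenuation law around a
gamma-variate bolus:

    C(t) = A (t - t0)^alpha exp(-(t - t0)/beta),  t > t0   (else 0)
    S(v, t) = B(v) exp(-k C_c(v)(t)) + noise

* `C(t)` is the concentration curve; its peak sits at `t0 + alpha*beta`.
  Defaults (`t0 = 12, alpha = 3.5, beta = 2`) put the signal nadir at
  timepoint 19, inside the 17–22 transit window typical of a
  50-measurement acquisition. A forward signal model is required because
  the analysis consumes signal, not concentration; the exponential
  attenuation `S = S0 exp(-kC)` is the simplest law that reproduces the
  characteristic transient signal *drop* of DSC imaging.
* `B(v)` is the voxel baseline: a constant `S0 = 100` plus a spatially
  correlated heterogeneity field (Gaussian-smoothed white noise, SD 5 by
  default) that gives healthy tissue texture for the texture families to
  respond to. The smoothing kernel width is a configuration knob
  (`texture_kernel_vox`, default 1.5 voxels).
* The compartment `c(v)` is either healthy tissue or lesion. Lesion voxels
  use a *delayed* (`delay`, the simulator's analog of the clinical
  Tmax > 6 s criterion — the acquisition repetition time is not modelled,
  so delays are expressed in timepoint units) and *attenuated*
  (`amplitude_factor`) bolus, plus an extra lesion-specific heterogeneity
  field (`texture_sd`).
* Noise is additive Gaussian (SD 2 by default), truncated at zero so
  intensities stay non-negative. Truncation is the smallest intervention
  that preserves the non-negativity invariant.

The outcome effect is planted **twice, independently**:

* globally — poor-outcome cases have their gamma scale broadened by
  `global_effect` (default +15 %), a whole-brain transit change;
* in the lesion — poor-outcome cases get `lesion_effect_delta` added to the
  lesion parameters (default: +2 timepoints delay, −0.15 amplitude factor,
  +4 heterogeneity SD).

Keeping the two mechanisms disjoint makes "combined features beat
single-region features" a *testable* property of the generator rather than
an artifact of shared signal. Effect sizes were fixed once at values that
make the cohorts clearly separable, emulating the strongly predictive
clinical setting this analysis targets; zeroing both deltas yields an
exactly label-exchangeable null cohort, which the calibration tests use.

Geometry: the brain is an ellipsoid filling ~80 % of the grid, the lesion a
smaller ellipsoid strictly inside it (construction fails otherwise). The
default grid is 48×48×12 voxels at 4×4×6 mm with T = 50 measurements and
42 good / 36 poor cases; a 256×256×20 grid can be configured where
clinical-scale realism matters more than runtime.

# Preprocessing

Two operations mirror standard DSC preprocessing on registered data
(registration and skull-stripping are out of scope; masks are inputs):

* **Temporal smoothing** — each voxel's time–intensity curve is replaced by
  a centered 1×3 moving average. Edges are handled by truncation
  (averaging only in-range samples) by default; this invents no data.
  Replicate padding is available for parity with implementations that pad.
  Smoothing is linear and never increases per-voxel temporal variance —
  both are asserted as properties in the tests.
* **Bolus-free average volume** — the voxelwise mean of the first *n* and
  last *n* volumes with denominator `2n` (default `n = 15` of `N = 50`),
  excluding the transit. Formulations of this average sometimes let the
  trailing window span `n + 1` volumes, which is inconsistent with the
  `2n` denominator; the implementation uses exactly the first and last
  `n`. Time indexing is 0-based (`S(0)…S(49)`) throughout.

Whether smoothing precedes the averaged volume is immaterial here: the
average volume is used for mask quality control only, and the feature
pipeline consumes the smoothed series.

# The radiomics engine

No radiomics engine exists in this package's R dependency stack, so the 93
base features are implemented natively (texture-matrix accumulation in
C++), with brute-force R enumerations as independent test oracles.

Per (volume, mask) pair the engine computes 18 derived images × 93
features = **1674** named features:

* the original image;
* 8 sub-bands of a single-level *stationary* 3D coiflets-1 wavelet
  transform (undecimated, periodic boundaries, band letters indexing the
  x/y/z axis filters). The stationary variant keeps sub-bands on the
  acquisition grid so the same mask applies; the count structure is
  basis-independent;
* Laplacian-of-Gaussian at sigma 1–5 mm (scale-normalized by sigma²,
  replicate boundaries). The five-sigma set is what the 18-member bank
  requires alongside the other standard filters;
* four monotone intensity remaps (square, square root, logarithm,
  exponential), each rescaled to the in-mask intensity range so a fixed
  discretization bin width stays meaningful on every derived image. Their
  normalization constants use only in-mask voxels, which keeps all
  features a function of the masked region (asserted by the far-field
  perturbation tests).

The six families and their cardinalities — first-order 18, GLCM 24,
GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14 — follow the de-facto standard
(IBSI-aligned) feature sets; shape features are excluded. Texture
aggregation is full-3D: 13 unique directions for co-occurrence and run
matrices with features averaged over directions, 26-connected zones for
GLSZM, the 26-neighbourhood for GLDM (dependence tolerance alpha = 0) and
NGTDM.

Discretization uses a fixed bin width (default 25 intensity units)
anchored at the in-mask minimum, so discretized features are invariant to
intensity shifts — a deliberate choice over multiple-of-bin-width
anchoring, which is only invariant to shifts that are multiples of the
width. No resegmentation or outlier clipping is applied. Degenerate cases
are defined, not propagated: a single occupied gray level yields zero
entropy, GLCM correlation 1, and finite values everywhere (an ROI under
two voxels is an error).

DRF naming is `<filter>_<family>_<feature>_<t>` with 0-based `t`, so
`wavelet-HHL_gldm_SmallDependenceLowGrayLevelEmphasis_1` is the value
computed on the second volume `S(1)`. For T = 50 a region contributes
83,700 DRF columns per case.

# Screening

Features are first normalized column-wise as `F* = (F − mean(F)) /
(max(F) − min(F))`. A mean-over-range normalization is unusual but is
the protocol this pipeline mirrors; the conventional z-score variant is
available behind `method = "zscore"`. Constant columns are excluded and
flagged. Two-sample t
p-values are invariant to affine per-column maps, so screening before or
after normalization is equivalent; the pipeline normalizes first.

Each feature then passes a Levene-gated two-sample t-test: a
homogeneity-of-variance test at 0.05 (Brown–Forsythe median centering by
default, matching the common default of the software stack this mirrors)
chooses between the pooled-variance t-test and Welch's t-test with
Satterthwaite degrees of freedom; features with `p < 0.05` are retained.
No multiple-testing correction is applied — fidelity to the raw `p < 0.05`
protocol — though a Benjamini–Hochberg option exists. Both test statistics
are computed vectorized across columns; scalar entry points
(`homogeneity_pvalue`, `two_sample_pvalue`) expose the same formulas and
are verified against `car::leveneTest` and `stats::t.test`.

Normalization (and, in the default `"paper"` selection mode, screening and
selection) is computed on the full cohort before cross-validation. This
reproduces the original protocol and its selection leakage; evaluation
reports carry an explicit note, and a `"nested"` mode
([`nested_evaluate()`]) re-runs screening and selection inside every
training fold for a leakage-free estimate.

# Lasso cascade

Selection solves the squared-error Lasso against the outcome coding
(good = 0, poor = 1 — the classification task is binary, so the binary
coding is the default; a raw-score regression coding would be a drop-in
since only `labels` changes):

    argmin  sum_i (y_i − b0 − sum_j b_j x_ij)^2 + lambda sum_j |b_j|

with an **unpenalized intercept** (penalizing `b0` would make selection
depend on the outcome's mean level, which no standard implementation
does). The penalty grid is 100 log-spaced values from the smallest lambda
with empty support (`max |x_j'(y − ȳ)| / M`) down to 1e-4 of it; lambda is
chosen by seeded, label-stratified 10-fold cross-validation minimizing
mean squared prediction error (glmnet's coordinate descent does the
fitting; the package contributes the grid, fold stratification and
reporting). Features with non-zero coefficients are "outstanding".

The cascade runs Lasso per region, concatenates the selected columns with
region-qualified names (`WB:`/`LL:` — same-named features from different
regions are different measurements and are never merged, so
`|combined| = |WB| + |LL|` always), and runs a second Lasso pass on the
concatenation. Duplicated column names within a region indicate a naming
bug and are a hard error.

# Evaluation

Ten classifiers are compared: Gaussian naive Bayes, cross-validated
logistic regression, a decision tree, gradient-boosted trees (100 rounds,
depth 3, learning rate 0.1), a multilayer perceptron with hidden layers
(400, 100) and L2 penalty 0.01, k-nearest neighbours (k = 5), AdaBoost of
stumps (50 rounds), linear discriminant analysis, a 200-tree random
forest, and an RBF-kernel SVM with class probabilities. Stated
hyperparameters are fixed; unstated ones take the backing
implementations' defaults. The MLP and AdaBoost are implemented natively
(full-batch Adam with early stopping on training loss; discrete SAMME
with depth-1 `rpart` stumps) because the installed stack offers no
multi-hidden-layer perceptron or stump-boosting classifier. Every model
emits a continuous positive-class score; models that fail to train are
recorded per-model without aborting the comparison.

Folds are stratified (each class shuffled by seed and dealt round-robin,
keeping per-fold class counts within one case of the global proportions).
AUC is the Mann–Whitney probability that a positive case outscores a
negative one, ties counted 1/2. Out-of-fold scores are pooled into one
AUC by default — every case contributes exactly once, which is the
lower-variance choice at n = 78 — with a mean-of-folds option. All model
randomness derives from the CV seed through a fixed splitting scheme, so
reports are reproducible.

# Numerical choices and degenerate inputs

* Discretization anchors at the in-mask minimum; entropies use base-2 logs
  over positive-probability cells only.
* Zero-variance features: excluded at normalization; within the t-test,
  two zero-variance groups give p = 1 (equal means) or the p → 0 limit.
* Constant features are excluded (and flagged) from outcome-correlation
  summaries.
* Lasso coordinate descent runs at threshold 1e-7; the orthonormal-design
  tests confirm soft-thresholding agreement to 1e-6.
* CSV serialization rounds to 10 significant digits so byte-level
  determinism of re-runs is assertable.

# Problem sizes used by the tests and acceptance script

Feature extraction cost scales as cases × T × filters × masked voxels, so
the stochastic suites run on reduced cohorts with the time axis compressed
by a factor of two relative to the defaults (t0 and beta halved, amplitude
rescaled by 2^alpha so the concentration curve is an exact time
compression, lesion delays halved): grid 12×12×6, T = 12, and a 2-member
filter subset. These sizes were chosen as the smallest at which the
transit window, both planted mechanisms and the texture families remain
expressed; the cascade and calibration behavior they exercise is
scale-free (count structure, calibration rates and oracle equivalences do
not depend on grid size). Null-calibration runs use 200 replicates of
80-case × 1000-feature Gaussian matrices; permuted-label and
group-ordering checks average 20 seeds. The full default-scale cohort
(48×48×12×50, 18 filters, 78 cases) is a multi-hour single-CPU
computation and is not exercised by the default test run.

# What passing tests do and do not show

The generator emulates the *statistical* structure the analysis assumes:
bolus-shaped signal drops, compartment-specific transit changes, spatially
correlated texture, exchangeable nulls. It does not emulate MR physics
(no arterial input function, no deconvolution, no Tmax computation, no
motion or registration artifacts), scanner-specific intensity
distributions, or clinically realistic lesion shapes. Passing tests
therefore establish that the pipeline is correctly implemented and
calibrated and that it recovers planted effects of the assumed kind — not
that any particular clinical AUC would be reproduced on real data.

# Known limitations

* The default-scale extraction is slow in a single process; there is no
  parallel or cached execution.
* The wavelet and LoG responses on low-range derived images can fall
  entirely inside one discretization bin, collapsing their texture
  features to constants; these columns are excluded at normalization
  rather than rescued by adaptive binning.
* Only binary outcomes are supported; no calibration curves or AUC
  confidence intervals are produced.
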