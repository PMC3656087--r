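---
title: "Gaussian process classification of grey-matter morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian process classification of grey-matter morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurogpc)
```

This vignette records how the package's statistical machinery works, the
assumptions behind it, and the design decisions taken where more than
one reasonable choice existed. It is the companion to the README's
worked example; nothing here asserts an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The data model

The unit of analysis is a modulated, smoothed grey-matter volume map:
voxel intensity is interpreted as local grey-matter volume after spatial
normalization, so group differences appear as localized intensity
differences. The package takes these maps as given (segmentation,
registration and modulation belong to upstream tools) and represents a
cohort as a manifest plus one NIfTI volume per subject.

An analysis mask selects voxels with intensity above 0.05 in at least
90% of subjects. Whole-brain pattern analyses always carry such an
implicit in-brain mask: background voxels contain no signal and only
inflate kernel computation. Both cut-offs are configurable
(`build_mask()`); the defaults are a mild relative threshold typical of
VBM practice. Voxels inside the mask are vectorized in a fixed linear
order (first array axis fastest), which is what makes weight-map
round-trips exact.

## Binary classifier

The classifier is a Gaussian process over the latent decision function
with a linear kernel on subject patterns,

K = s · X Xᵀ (centered) + b,

and a probit likelihood. Three kernel conventions matter:

- **Centering** is done in feature space per training fold (the test
  column of the kernel is centered with the training means), never with
  test data, so cross-validation stays leakage-free. For a linear
  kernel, computing K once on all subjects and slicing fold blocks is
  algebraically identical to per-fold recomputation; a unit test asserts
  this identity.
- **Normalization** divides K by its mean diagonal. This is purely a
  conditioning choice fixing the working scale near 1.
- **Bias** b (default 1) adds a constant kernel component, equivalent to
  an unpenalized-ish intercept with prior variance b. Without it, a
  centered zero-mean GP cannot represent the class-frequency offset: all
  predictive probabilities compress symmetrically around 0.5, and
  thresholding them at the training frequency of the patient class
  systematically over-calls the patient class in unbalanced designs. We
  observed exactly this failure on synthetic unbalanced cohorts, which
  is why the bias term defaults on.

The kernel scale s is selected per training fold from a grid
(default 10⁰…10⁴) by the approximate log marginal likelihood of that
fold's training set. A fixed unit scale is also supported
(`scale_grid = NULL`); with a unit-normalized kernel it yields weakly
confident probabilities whose ranking (AUC) is fine but whose spread is
small. Per-fold selection keeps hyperparameter choice inside the
training data, avoiding test leakage.

**Expectation propagation.** The probit posterior is approximated by EP
with the standard moment-matching site updates: tolerance 1e-6 on the
largest site-parameter change, at most 100 sweeps, multiplicative
damping 0.8 for stability on near-separable problems, and a full
Cholesky recomputation of the approximate posterior after every sweep to
contain rounding. Site precisions are clamped nonnegative and cavity
precisions floored at 1e-12. Non-convergence is an error carrying the
last site change, never a silent result. The test suite certifies EP
against an independent tensor-product Gauss–Hermite quadrature of the
exact posterior on all toys with n ≤ 4, at 1e-3 absolute error in
predictive probability. Negative predictive variances arising from
rounding are clamped at zero with a warning; probabilities are kept
strictly inside (0, 1).

## Multiclass classifier

The 3-class design uses one latent function per class with a shared
kernel, a softmax likelihood, and the Laplace approximation at the
posterior mode. Newton iterations exploit the block structure of the
softmax Hessian (one Cholesky per class plus a cross-class factor);
convergence requires the gradient of the log posterior below 1e-6 in
max-norm, at most 50 iterations, with the iteration trace reported on
failure. The approximate marginal likelihood uses the factorization
log|I + K_blk W| = Σ_c log|B_c| + log|Σ_c E_c| — the cross-class term is
not optional; omitting it biases scale selection toward small scales
(we verified the factorization numerically against the dense
determinant).

The softmax expectation over the latent predictive Gaussian has no
closed form; it is evaluated by fixed-seed Monte Carlo with 10,000
draws. Consequences accepted deliberately: predictions are reproducible
given the seed, exact class-permutation equivariance holds for the
latent quantities but only to Monte Carlo accuracy (~1/√draws) for the
final probabilities, and "uniform probabilities at an uninformative test
point" is likewise a statement up to Monte Carlo error. The covariance
square root uses a symmetric eigendecomposition with negative
eigenvalues clamped at zero.

Categorical multiclass calls take the argmax of probabilities divided by
training-class frequencies — the exact generalization of binary
frequency thresholding (in the two-class case the two rules coincide).
This convention deliberately makes rare classes easier to call; on
cohorts where one group is a "reference" with no distinctive pattern,
its uncertain members drift toward the rarest class. That is a property
of the decision rule, not of the probabilities.

## Cross-validation and inference

Balanced two-group designs use leave-one-pair-out: each fold removes one
patient/control pair, keeping every training set balanced. The pairing
key is age (each group sorted by age, paired by rank), the matching
variable reported for cohorts of this kind; an explicit pairing can be
supplied. Unbalanced and multiclass designs use leave-one-subject-out.
The per-fold decision threshold is always that fold's training-class
frequency; a probability exactly at the threshold goes to the patient
class (a deterministic tie rule that favors sensitivity).

The permutation test permutes labels across the whole sample (preserving
group sizes), re-derives the pairing from the permuted labels, and
repeats the entire cross-validation per permutation; the statistic is
balanced accuracy. The p-value is the fraction of permutations with
accuracy at least the observed value, so p = 0 is representable; the
positively biased but never-zero estimate (b+1)/(m+1) is reported
alongside. Counting "at least" rather than "strictly above" keeps the
p-value valid (conservative under ties) — with a discrete statistic such
as balanced accuracy, strict counting would be anti-conservative. The
suite checks the type-I error of the whole procedure on 200 null
cohorts (10 vs 10 subjects, 16³ grids, 99 permutations each — sizes
chosen so the calibration experiment completes in minutes) against the
binomial band around 0.05.

Probability–covariate correlations are plain Pearson correlations of the
predicted patient probability against age, IQ and clinical scores,
computed within each diagnostic group; zero-variance covariates yield a
flagged NA, never a silent 0.

## Weight maps

For a linear kernel the latent predictive mean is x*ᵀ w with
w = Xᵀ α, where α are the dual coefficients of the fitted posterior
((K + Σ̃)⁻¹ μ̃ for EP; y − π̂ at the Laplace mode, per class). Weights are
reported raw (no normalization); the sign convention fixes positive
weights as evidence for the patient class. Displayed maps are trained on
the full sample — the convention for single published weight maps —
while per-fold maps remain computable for stability analyses. The
default display threshold keeps voxels with |w| above 40% of the maximum
absolute weight, pooled across signs so both strong positive and strong
negative voxels survive; a per-sign variant is available since the
pooled rule suppresses the weaker sign entirely when the map is very
asymmetric.

## Univariate arm

Voxel-wise pooled-variance two-sample t-tests (direction: first group
minus second; zero-variance voxels excluded and counted) are followed by
cluster-level inference: connected components (26-connectivity, per
sign) above the |t| threshold corresponding to a two-sided voxel
p (default 0.001). Family-wise-corrected cluster p-values come from the
permutation distribution of the maximum cluster extent under group
relabeling; uncorrected cluster p-values from the pooled null
distribution of all permutation cluster extents. Permutation-based
max-statistic correction was chosen over random-field theory
deliberately: it is assumption-free (no smoothness estimation or
stationarity adjustment needed), honors the same family-wise error
contract, and its calibration is directly testable — the suite measures
the realized FWE on 120 null cohorts at the working 32³ resolution.
Global tissue comparisons (GM/WM/CSF/TIV in ml, with TIV = GM+WM+CSF)
use the same pooled-variance t-test.

## Synthetic cohorts: what they emulate, and what not

`generate_cohort()` builds each subject as
template × (1 + group effect field) + smoothed noise, with

- a smooth nonnegative grey-matter template, zero outside an ellipsoidal
  brain mask;
- multiplicative spherical effects (signed fractional change of local
  template intensity), so effects scale with local grey-matter density
  as in modulated VBM data and intensities stay nonnegative;
- subject noise smoothed with the same FWHM as the template (8 mm
  default), giving VBM-like spatial autocorrelation;
- covariates drawn per group from normal distributions matching the
  demographic/clinical table of the motivating three-group adolescent
  cohort, independent of the images by default; an optional coupling
  coefficient scales a subject's effect magnitude with their
  standardized clinical score for correlation experiments.

Default conditions: groups ADHD 29 / control 29 / ASD 19; 32³ grid of
4-mm voxels (desk scale — the full pipeline including permutations runs
in minutes); pre-smoothing noise SD 0.4 (≈0.077 after 8-mm smoothing,
against template intensities ≈0.5); two ADHD reductions (−12%, −10%)
and one ASD reduction plus one ASD increase (−12%, +10%) at distinct
sites. No published effect sizes exist for these grey-matter contrasts,
so the amplitudes are free parameters chosen once to give a clearly
detectable but not trivially separable signal; they are not calibrated
to any reported result, and the accuracies the acceptance script prints
are properties of these synthetic conditions, not reproductions of any
clinical value.

What the generator does **not** emulate: registration/segmentation error
fields, scanner or site effects, non-Gaussian intensity distributions,
spatially varying smoothness, or correlated anatomical covariance
between distant regions. Passing tests therefore certify the
statistical machinery (calibration of permutation inference, recovery
of injected effects, metric arithmetic), not performance on real MRI
data.

## Known limitations

- EP and Laplace are approximations; the quadrature certificate covers
  small n only, and the Laplace softmax probabilities are known to be
  conservative (compressed toward uniform) relative to the EP probit in
  the degenerate two-population case — the suite checks ordinal
  agreement, not numerical identity, between the two.
- The linear kernel is the only kernel; that is what makes weight maps
  exact, and non-linear kernels are out of scope.
- Balanced-accuracy permutation p-values are discrete; with few
  permutations the attainable p-values are coarse.
- The matched pairing is derived from age alone; if matching in a real
  cohort used additional variables, supply the pairing explicitly.
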