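# neurogpc

Probabilistic diagnostic classification of structural brain morphometry.

Voxel-based morphometry (VBM) produces, for every subject, a smoothed
modulated grey-matter volume map: a 3D image whose intensities measure
local grey-matter volume after spatial normalization. `neurogpc` asks
the individual-level question that group statistics cannot answer —
*given this subject's grey-matter pattern, how probable is it that they
belong to the patient group?* — using Gaussian process classification
(GPC) over whole-brain patterns, and couples it with the conventional
mass-univariate voxel-wise comparison so multivariate and univariate
views of the same cohort can be compared directly. The motivating use
case is differential diagnosis of neurodevelopmental disorders
(ADHD vs typically developing controls, and its disorder specificity
against autism spectrum disorder), but nothing in the code is specific
to those labels.

It is aimed at neuroimaging methodologists and statisticians who want a
self-contained, fully tested reference implementation: every stage runs
on synthetic cohorts generated by the package itself, so the complete
pipeline — including its permutation inference — is verifiable without
access to any clinical dataset.

## The model

Subjects' masked grey-matter maps are vectorized into a pattern matrix
`X` (subjects × voxels) and enter a linear kernel `K = X Xᵀ`
(mean-centered per training fold, unit-normalized, plus a constant bias
component that lets the latent function carry a class-frequency
intercept). A zero-mean Gaussian process prior over the latent function
f with this kernel, combined with:

- a **probit likelihood** for binary designs, approximated by
  **expectation propagation (EP)** — iterative moment matching of the
  non-Gaussian posterior, giving the predictive probability
  `p(y*=patient | x*) = Φ( μ* / √(1 + σ*²) )`;
- a **softmax likelihood** for the 3-class design, approximated by the
  **Laplace method** at the posterior mode, with Monte Carlo integration
  of the softmax over the latent predictive Gaussian.

Categorical calls threshold the predictive probability at the
training-set frequency of the patient class (0.5 when balanced);
performance is summarized as sensitivity, specificity, PPV/NPV,
**balanced accuracy** (mean of sensitivity and specificity), ROC **AUC**
(normalized Mann–Whitney statistic), and **target information** in bits,
`TI = H(class frequencies) + mean log₂ q_i`, the information gain over a
classifier that always emits the class frequencies. Significance of the
balanced accuracy comes from label permutations that re-run the entire
cross-validation. Because the kernel is linear, the classifier's
discriminative direction back-projects to a voxel-space **weight map**
`w = Xᵀα`; displayed maps are conventionally thresholded at 40% of the
maximum absolute weight. The univariate arm computes pooled-variance
two-sample t-tests per voxel with cluster-level family-wise error
control by permutation of the maximum cluster extent (26-connectivity).

The synthetic cohort generator emulates the post-preprocessing study
conditions: three groups (ADHD n=29, control n=29, ASD n=19), smoothed
(8-mm FWHM) nonnegative grey-matter templates on a 32³ grid of 4-mm
voxels, localized multiplicative group effects, and group-structured
covariates (age, IQ, Conners' ADHD T-score, SDQ hyperactivity score).

## Worked example

A balanced two-group run on a small synthetic cohort with one injected
grey-matter reduction in the patient group:

```r
library(neurogpc)

spec <- cohort_spec(group_sizes = c(ADHD = 16L, control = 16L),
                    image_shape = c(24L, 24L, 24L),
                    effects = list(effect_blob(c(9, 11, 10), 12, -0.15, "ADHD")),
                    seed = 42L)
cfg <- run_config(cohort = spec, design = "binary-balanced",
                  n_perm = 99L, vbm_n_perm = 99L, seed = 42L)
report <- run_pipeline(cfg)
report
#> <pipeline_report> design: binary-balanced | n = 32
#> TP 11  FP 5  TN 11  FN 5
#> sensitivity 68.8%  specificity 68.8%
#> PPV 68.8%  NPV 68.8%  balanced accuracy 68.8%
#> AUC 0.781 | target information 0.113 bits
#> permutation test (binary): observed balanced accuracy 68.8%
#> 99 permutations: p = 0.0303 (smoothed 0.04)
```

Reading this: out of 16 patients, 11 were called correctly from their
grey-matter pattern alone (sensitivity 68.8%), likewise 11 of 16
controls; chance would be 50%, and only 3 of 99 label permutations
reached the observed balanced accuracy, so the classification is
significant at p ≈ 0.03. Per-subject predictive probabilities are in
`report$results`; e.g. the first patient is called at p(ADHD) = 0.68
while a borderline one sits at 0.48 and is miscalled — the probability
quantifies that diagnostic uncertainty. The univariate arm finds the
injected reduction as a significant cluster:

```r
report$vbm$clusters[, c("direction", "extent_voxels", "peak_t", "p_fwe")]
#>   direction extent_voxels   peak_t     p_fwe
#> 1  positive            46 6.786807 0.0000000
#> 2  positive             1 4.083930 0.9494949
#> 3  positive             1 4.155336 0.9494949
```

(the contrast is control − ADHD, so a "positive" cluster is a
grey-matter deficit in the patient group; only the 46-voxel cluster
survives family-wise correction). `report$weight_maps` holds the
discriminative weight map and its 40%-of-maximum thresholded version,
writable as NIfTI via `write_weight_map()`.

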