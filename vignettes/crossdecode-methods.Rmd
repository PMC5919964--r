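---
title: "Cross-modal decoding and predictive pattern decomposition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal decoding and predictive pattern decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

CrossDecode implements a two-stage multivariate analysis of trial-wise fMRI
activity maps built around one scientific question: do written action words
(verbs) and pictures of action-implying scenes share a neural code that a
classifier can exploit, distinct from the code shared by nouns and pictures
of plain objects?

**Stage 1 — cross-modal generalization.** A linear support-vector machine is
trained to separate verb from noun trials using only word-evoked maps, then
applied unchanged to picture-evoked maps, scoring implied-action pictures as
"action" and plain objects as "non-action". Features are voxels inside a
meta-analytically defined "mirror system" search volume, standardized with
training statistics, optionally reduced by recursive feature elimination
(RFE). Because the test maps come from different stimuli, different
conditions, and are never touched during training or feature selection,
above-chance accuracy is evidence of a modality-independent action/object
code. Accuracy is judged by the exact one-sided binomial tail probability at
chance 0.5, and its stability by jackknife (leave one subject out), subject
bootstrap (100 replications) and split-half (100 iterations) reruns.

**Stage 2 — predictive pattern decomposition.** Semi-supervised factored
logistic regression decomposes the maps into k = 10 latent spatial
components that simultaneously reconstruct the data (a linear bottleneck
autoencoder) and predict the four conditions (a softmax read-out sharing the
same latents). The result is a set of component maps plus a 4 x k table of
per-condition contributions.

The study's scanner data are not deposited, so the package ships a seeded
generator that emulates the design (20 subjects x 60 modelled trials x 4
maps per trial = 4800 maps, split 2400/2400 by modality) with a known latent
structure, making every stage testable end-to-end.

# The synthetic world

`generatorConfig()` states the world once; tests never tune it after seeing
results.

* **Design sizes** (20 subjects, 60 trials, 4 maps/trial) are the emulated
  study's numbers. The published description of trial structure is
  internally inconsistent (one map per trial vs. four); the generator
  follows the arithmetic that reproduces the printed totals — 1200 trials,
  4800 maps, a 2400/2400 modality split — and exposes `mapsPerTrial`.
* **Grid** 20 x 24 x 20 voxels, a 9 mm stand-in covering the same MNI
  bounding box as the full 60 x 72 x 60 3 mm space (`mniGrid()` scales the
  voxel size with the shape). Full resolution is available but pointless at
  test scale.
* **Components** are unit-norm 3-D Gaussian blobs (sigma 1.5 voxels) at
  seeded random centres kept at least 3 sigma apart, which keeps pairwise
  map correlations near 0.1 (enforced < 0.3): smooth, localized patterns
  without modelling hemodynamics. With a mask supplied, centres are drawn
  inside it so the search space contains the signal.
* **Loadings** over (noun, verb, object, implied_action): an action
  signature (0, +a, 0, +a); an object signature (+o, -o, +o, -o) — common
  activation for objects and nouns, common decrease for actions and verbs;
  word- and picture-specific modality components; constant "background"
  components that vary only between subjects. The action column uses the
  zero (not opposite) option on noun/object so the two signature columns are
  not collinear. Note a consequence: because the object signature is itself
  an action/non-action contrast, a dataset with `actionEffect = 0` but
  `objectEffect > 0` still carries a transferable signature; true null
  worlds for type-I-error checks therefore zero both amplitudes.
* **Noise**: i.i.d. Gaussian map noise (sd 1 against unit-amplitude
  effects), plus a multiplicative per-subject, per-component amplitude
  jitter, Gaussian with mean 1 and sd 0.2 — the simplest between-subject
  heterogeneity that makes subject-resampling analyses meaningful. No
  autocorrelated scanner noise or drift: the analysis operates on trial
  beta maps, not time series.

A green test on this world establishes that the estimators behave as
specified under smooth, low-rank, Gaussian conditions. It does not establish
robustness to real fMRI artifacts (motion, physiological noise, spatially
correlated noise, inter-subject anatomical misalignment).

# Volumes and standardization

* NIfTI-1 I/O is implemented in the package (no NIfTI reader exists in the
  supported R stack): single-file `.nii`/`.nii.gz`, both endiannesses, the
  common scalar datatypes, sform/qform affines. Volumes are reoriented to
  canonical RAS+ on load when the affine is axis-aligned up to permutation
  and flips; oblique affines are left as stored with a warning. This
  removes the orientation ambiguity that voxel-index-based analyses
  otherwise inherit.
* Coordinates are 0-based voxel indices mapped to MNI mm by the affine.
* The search-space mask is built as a union of spheres (default radius a
  config parameter) around published peak coordinates — the published
  cluster extents themselves are unavailable, so spheres stand in.
* Gray-matter masking keeps voxels with at least 10% tissue probability.
* Standardization mean-centres and unit-variance scales each voxel using
  **training statistics only** (population variance, divide by n; the
  distinction is immaterial at n = 2400). Columns constant in training are
  set to zero in train and test: they carry no information and would
  otherwise divide by zero.

# The classifier and the significance test

No SVM solver ships with the supported R stack, so the package minimizes
the L2-regularized squared-hinge objective
`0.5 ||w||^2 + C sum_i max(0, 1 - y_i (x_i w + b))^2`
directly with L-BFGS and analytic gradients (hinge loss available by flag;
C defaults to 1 and is exposed). Zero initialization makes the fit
deterministic. Squared hinge is the default because it is differentiable,
which L-BFGS requires for reliable convergence; at these sample sizes the
two losses select near-identical voxel rankings.

RFE halves the retained voxel set each step (floor rounding, ties in
|weight| broken toward the lower voxel index for determinism), refitting on
training data only. No stopping criterion is published for "the optimal
number of predictive voxels"; the package runs to a floor of 16 voxels and
uses the step with the best 5-fold cross-validated training accuracy, with
folds grouped by subject so one subject's maps never straddle a fold.

The binomial test is the exact tail sum `P(X >= nCorrect)` computed in log
space. Sidedness is not published; the package defaults to one-sided
(the hypothesis is directional — decoding above chance) with a two-sided
flag. Predictions are scored per map, because the published denominator
(2400) equals the map count, not a trial count; majority-vote aggregation
per trial is available via `byTrial`.

The bootstrap resamples subjects (not trials), consistent with the
subject-wise jackknife; resampled duplicates are relabelled as distinct
pseudo-subjects so grouped cross-validation still separates them.

# Semi-supervised factored logistic regression

With encoder `h = X W_enc + b_enc`, the objective is

    lambda * CE(softmax(h W_cls + b_cls), y)
      + (1 - lambda) * mean((h W_dec + b_dec - X)^2)
      + l1 * sum |W| + l2 * sum W^2
      + ortho * sum_{i != j} Cov(h)_ij^2

trained by minibatch RMSProp (`a <- rho a + (1 - rho) g^2`,
`theta <- theta - lr g / (sqrt(a) + eps)`) with global gradient-norm
clipping. Stated values: lambda 0.5, lr 1e-4, rho 0.9, eps 1e-6, at most
500 epochs, Gaussian init scaled by 0.004, zero biases, k = 10.

Design choices where the published account is silent:

* **Linear, untied encoder/decoder.** The module is described as a
  generalization of PCA/ICA; linearity is the weakest matching assumption
  and makes the PCA-limit test exact: at lambda = 0 with no penalties the
  optimum is the rank-k PCA reconstruction, and training must come within
  5% of it. At lambda = 1 with k >= 4 the model is exactly a bottleneck
  multinomial logistic regression and must match a direct fit within 2
  accuracy points.
* **Penalty coefficients** l1, l2, ortho are unpublished; defaults are
  l1 = l2 = 0.001 and ortho = 0.1, all exposed in the config. The
  Elastic-Net defaults are deliberately small: RMSProp normalizes each
  coordinate's step by its gradient magnitude, so a constant L1 subgradient
  comparable to the data gradients makes every weight oscillate around zero
  and training freezes — stronger sparsity penalties demand a solver with
  explicit soft-thresholding, which the stated optimizer is not. Tests use
  ablation contrasts (with vs. without), never absolute values. Biases are
  unpenalized (penalizing intercepts distorts calibration).
* **"Component covariance"** is read as the latent-activation covariance
  (population covariance of `h` over the batch); the spatial decoder Gram
  matrix is available via `orthoTarget = "spatial"`.
* **Clipping threshold** 5.0 and **batch size** 100 are unpublished
  defaults; batch order is reshuffled per epoch under the run seed.
* **Contributions** of component j to condition c are defined as
  `W_cls[j, c] * sd(h_j)` — the classifier weight scaled by how much the
  component actually varies over the data, making columns comparable. The
  published figures do not define "relative contributions" operationally;
  this is the package's own operationalization. Per-component signs are a
  gauge freedom (flipping decoder row, classifier row and latent together
  changes nothing), so only sign *patterns* across conditions are
  interpretable.
* **Reconstruction scaling.** The MSE is a mean over all entries, which
  makes the reconstruction gradient scale like 1/nVoxels. Consequences for
  practice: at realistic voxel counts the stated learning rate 1e-4 trains
  the classifier long before the autoencoder, and minibatch noise can
  dominate the decoder's drift. The parameter-recovery and limit tests
  therefore train full-batch with a larger learning rate (5e-3); these
  settings are test-world choices, not new defaults.
* **Divergence** (non-finite loss) aborts with a diagnostic rather than
  returning garbage.
* Exported component maps are z-scored over in-mask voxels per component,
  matching the "z-values" convention for published maps.

The parameter-recovery test world deserves a note: the canonical action and
object signatures are strongly negatively correlated *as latent scores*
(both are action/non-action contrasts), which makes exact recovery of those
two components ill-posed — any rotation mixing them reconstructs equally
well. The recovery world therefore uses three mutually orthogonal condition
contrasts (modality, object-vs-action, interaction) with distinct
amplitudes, an identifiable design under which best-match |r| >= 0.8 is a
meaningful bar.

# The pipeline

`runPipeline()` chains mask construction, simulation, masking, decoding,
perturbations and decomposition. One global seed deterministically derives
per-stage seeds by hashing the stage name, so stages are independently
reproducible and a rerun with the same config reproduces the decoding
exactly. Reports are JSON (machine) plus `renderReport()` text (human).
Configurations serialize to JSON — not YAML — because no YAML parser is in
the package's guaranteed dependency set; the round trip is lossless.

The package deliberately exposes the pipeline as R functions rather than a
shell program; `scripts/acceptance.R` shows the end-to-end invocation.

# Known limitations

* The generator's Gaussian-blob world cannot probe sensitivity to realistic
  noise spectra, anatomical variability, or preprocessing choices (those
  live upstream of beta maps and are out of scope).
* The squared-hinge L-BFGS SVM is an equivalent formulation, not the exact
  solver used originally; published accuracies additionally depend on the
  real data and are not reproducible at desk scale. The worked-example
  statistics (54%, p <= 0.000186 from 1292/2400) are recomputed exactly.
* RFE cross-validated model selection is the package's own stopping rule;
  with a different rule the selected voxel count (not the path) may differ.
* The factored model's published penalty coefficients are unknown;
  conclusions should rest on ablation contrasts, as in the test suite.
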