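---
title: "Methods: texture-based ultrasound nodule classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based ultrasound nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models each
stage implements, the assumptions they rest on, the parameters that matter
and their defaults, the numerical choices made where the design was
genuinely open, and what the synthetic data can and cannot tell you about
performance on clinical images.

## The problem

Thyroid nodules are discrete lesions graded on B-mode ultrasound as benign
or malignant; the definitive label comes from fine-needle aspiration and
pathology. Malignant nodules tend to show finer, higher-contrast,
more heterogeneous echotexture than benign ones. The pipeline turns that
observation into a classifier: enhance texture, summarize it with
second-order and multiscale statistics, and boost weak threshold rules
into a strong ensemble. Labels are coded 0 = benign, 1 = malignant, and
malignant is the positive class everywhere (sensitivity is the malignant
detection rate).

## Synthetic study conditions

Clinical ultrasound archives are rarely shareable, so the generator in
`synthetic_config()`/`generate_dataset()` defines the study conditions the
package is exercised under. Each image is

```
pixel = clip( (base + contrast * smooth(latent, correlation_length)) * speckle + noise, >= 0 )
```

where `latent` is a pixelwise standard Gaussian field, `smooth` is a
Gaussian blur at the class's correlation length (standardized back to unit
variance, so `contrast` is the texture standard deviation in gray levels;
an optional orientation elongates the blur kernel 4:1 for striated
texture), `speckle` is unit-mean multiplicative Gamma noise with shape `k`
(scale 1/k) — the standard B-mode speckle emulation — and `noise` is
additive Gaussian acquisition noise. Speckle multiplies the echo intensity
(base plus texture): applying a unit-mean multiplicative field to a
zero-mean texture component alone would collapse to symmetric additive
noise and lose the defining property of speckle, that its amplitude scales
with echo strength.

Defaults: 64×64 images, 322 malignant : 128 benign class balance, benign
texture (base 120, correlation length 5 px, contrast 18), malignant
texture (base 110, correlation length 2.5 px, contrast 36), speckle shape
3, noise sd 8. The texture contrast ratio and correlation lengths were
calibrated once so that the default task difficulty matches the clinical
operating point this kind of CAD system reports — held-out accuracy in the
low-to-mid 90s with imperfect specificity — rather than a trivially
separable toy: a generator whose two classes separate perfectly (accuracy
and AUC of 1.0) would say nothing about the ensemble's advantage over a
single feature threshold, and nothing about the regime the method is
actually used in.

What the generator does *not* emulate: beam physics, depth-dependent
attenuation and focus, anisotropic speckle cell shape, acoustic shadowing,
calcifications, nodule boundaries and halo signs, or patient-level
correlation between images (each image is an independent sample; clinical
sets often contain several images per patient). Passing tests on this
generator therefore demonstrate the pipeline's internal correctness and
its ability to exploit second-order texture differences — not clinical
performance.

Images save as 16-bit grayscale TIFF plus a `filename,label` CSV manifest
and a JSON config snapshot. Pixels are clipped to [0, 65535] and rounded
at save time; loading returns exactly those quantized values, so the
round trip is exact up to the documented 16-bit quantization.

## Hybrid Wiener–Gabor preprocessing

`wiener_filter()` is the pixelwise adaptive minimum-MSE denoiser built
from local first and second moments over an odd window (default 3×3,
matching the kernel size used throughout the package's 2-D smoothing):

```
out = mu + max(s2 - nv, 0) / max(s2, eps) * (x - mu)
```

When the noise variance `nv` is unknown it is estimated as the mean local
variance, the standard data-driven choice. Flat regions (s2 ≤ nv) collapse
to the local mean; strongly textured regions pass nearly unchanged. The
filter assumes additive, approximately stationary noise — it is applied
before any multiplicative-to-additive consideration and is deliberately
simple and fast.

`gabor_kernel()` is a Gaussian envelope times a complex sinusoidal
carrier: with (row, col) offsets rotated into the orientation frame,
`z1 = f cosθ + g sinθ`, `z2 = −f sinθ + g cosθ`,

```
G = A * exp(-0.5 * (z1²/σ1² + z2²/σ2²)) * exp(i * 2π F z1)
```

The complex form gives a phase-insensitive response magnitude
(`θ` and `θ+π` are equivalent). `gabor_bank()` defaults to the
4 frequencies × 4 orientations cross product above with σ = 2 px and 9×9
kernels; `hwgf_preprocess()` takes the per-pixel **max** magnitude over
the bank (configurable to mean), then min–max rescales to [0, 1]. An
input with no dynamic range maps to all zeros. Max combination keeps the
strongest oriented band-pass response at each pixel, which is what the
downstream co-occurrence statistics should see; mean combination smooths
across orientations and dilutes anisotropic structure.

All convolutions (`convolve2d()`) are true convolutions (kernel flipped),
same-size output, with half-sample symmetric reflection padding — the
conventional choice that avoids the dark frame zero padding would
introduce into local statistics.

## Co-occurrence features

`quantize_image()` bins each image linearly between its own minimum and
maximum into L equal-width levels (default L = 32 — fine enough to keep
texture gradations, coarse enough that an 8×8 neighborhood populates the
matrix; configurable). A constant image maps to level 0. Note the
consequence: quantization is scale- and offset-invariant per image, so
absolute contrast registers in the features only relative to fixed noise
floors, not directly. This is why the generator's class separation runs
through correlation length and texture-to-noise ratio rather than raw
amplitude, and why the test suite's separability check turns the noise
stages down to isolate the texture knob.

`compute_glcm()` counts pairs of quantized values at a signed (row, col)
displacement; the four offsets `(0, Δ)`, `(−Δ, Δ)`, `(−Δ, 0)`,
`(−Δ, −Δ)` sweep 180° at distance Δ (default 1). Accumulation is
asymmetric — no transpose-symmetrization — because rotational coverage
comes from the sweep itself; a `symmetric` flag is provided. All ten
statistics are transpose-invariant, which yields an exact 90°-rotation
invariance of the orientation-averaged feature vector (verified to 1e-10
in the tests).

The ten statistics use 0-based level indices q, z and the normalized
matrix P: autocorrelation Σ q z P; contrast Σ (q−z)² P; correlation
Σ (q−μe)(z−μg) P / (σe σg); cluster prominence and shade
Σ (q+z−μe−μg)^{4,3} P; dissimilarity Σ |q−z| P; energy Σ P²; entropy
−Σ P log₂ P (bits, 0·log 0 ≡ 0); homogeneity Σ P / (1 + (q−z)²); maximum
probability max P. Homogeneity uses the squared-difference denominator
(the inverse difference moment): it keeps the statistic within (0, 1],
equal to 1 exactly when all mass is diagonal, and avoids the singular
denominator a signed first-power difference would produce at q − z = −1.
When a marginal is degenerate (σe σg = 0, e.g. a constant image) the
correlation is reported as 0 and the vector carries a
`degenerate_marginal` attribute rather than erroring: a constant patch
has no defined linear association, and 0 is the neutral value for a
downstream classifier. Orientation pooling is the arithmetic mean of the
ten features over the four offsets.

## Wavelet subband energies

`dwt2_decompose()` is a separable periodized filter-bank decomposition
with Haar and db2 (4-tap Daubechies) filters; the high-pass is the
quadrature mirror of the low-pass. Periodization keeps the transform
exactly orthogonal, so total squared-coefficient mass equals squared-pixel
mass (asserted to 1e-8), at the price of wrap-around artifacts on
non-periodic content — acceptable here because only aggregate subband
energies are used. Subband names give the filter along the row index then
the column index: LH (row-low/col-high) carries vertical features, HL
horizontal features, HH diagonal; the mapping is fixed behaviorally by the
stripe tests (horizontal stripes, i.e. variation across rows, dominate
HL). Images must have even dimensions at every level, and the DWT is not
shift-invariant — tests use fixed alignment, and features from shifted
images will differ.

`wavelet_energy_features()` reports, per level, each subband's mean
squared coefficient normalized by the four subbands' total at that level,
so each level contributes 4 shares summing to 1. Defaults: db2, one
level. db2 is the shortest Daubechies filter with a vanishing moment
beyond Haar's, a reasonable texture default; Haar is kept for exact
hand-checkable tests. The "adaptive" element of the wavelet stage is
realized as data-driven selection: `select_wavelet()` scores candidate
(family, depth) pairs by k-fold cross-validated boosted-stump accuracy on
the training split only and returns the winner; the pipeline default
keeps the fixed db2/level-1 choice unless the user opts in, keeping the
default path deterministic and cheap.

## AdaBoost ensemble

`fit_stump()` exhaustively searches features × thresholds × polarities
for the minimum weighted 0/1 error, computed by cumulative sums over each
sorted feature (O(n log n) per feature). Candidate thresholds are the
midpoints of consecutive sorted unique values **plus one threshold below
the minimum**. The extra candidate makes the two constant classifiers
representable, exactly as a depth-1 decision tree whose leaves agree.
This matters: a weighted-majority vote of one-sided threshold stumps
alone provably cannot represent an interval class in one dimension (for
the four-point pattern x = 1,2,3,4 with labels 0,1,1,0, the vote margins
at the two endpoints sum to zero identically, so they can never both be
classified 0) — with constant stumps admitted, boosting fits that pattern
in three rounds. Ties are broken deterministically: lowest error, then
lowest feature index, lowest threshold, `≤`-polarity first.

`train_adaboost()` runs the classical discrete AdaBoost recurrence:
uniform initial weights, per round the best stump with weighted error
ε_t, reweighting correct examples by β_t = ε_t/(1−ε_t) and renormalizing
(equivalently: misclassified examples end the round holding exactly half
the mass). A perfect round (ε_t = 0) is retained with β_t floored at
1e-10 and stops training; a round at or above 0.5 is dropped and stops
training, so every retained β_t ∈ (0, 1) and every vote weight
log(1/β_t) > 0. T defaults to 50 rounds. Training is fully deterministic
given the data ordering. `predict()` applies the weighted-majority rule
H(x) = 1 iff Σ log(1/β_t) h_t(x) ≥ ½ Σ log(1/β_t) and exposes the margin
(left side minus right side) as the continuous score for ROC analysis.
Models serialize to JSON.

The final feature vector concatenates the ten co-occurrence features with
the wavelet energy shares (selection between the two blocks, rather than
concatenation, can be emulated by training on a column subset).

## Evaluation statistics

`classification_metrics()` computes accuracy (tp+tn)/total, sensitivity
tp/(tp+fn) and specificity tn/(tn+fp); a zero denominator yields `NA`
plus an `undefined` flag instead of an error, since small or degenerate
test splits are a legitimate state to report. `roc_curve()` sweeps the
unique scores as thresholds (positive when score ≥ t) and integrates by
trapezoid; this equals the Mann–Whitney probability with half credit for
ties (the all-tied degenerate case gives exactly 0.5), verified against
an O(n²) pair-counting oracle to 1e-12.

`logistic_fit()` implements maximum-likelihood logistic multiple
regression by iteratively reweighted least squares with an intercept:
convergence when the maximum absolute score falls below 1e-8 (or 100
iterations), Wald standard errors from the inverse observed information.
Weights are floored at 1e-12 to keep the information matrix invertible in
saturated regions. Complete or quasi-complete separation — diverging
coefficients (|β| > 15 on the linear predictor scale) or fitted
probabilities within 1e-10 of 0/1 — is flagged with a warning and
`separation = TRUE`, never an exception, because separation is a property
of the data worth reporting, not a numerical failure. The implementation
is in-repo so the risk-factor analysis is part of the tested artifact;
the test suite cross-checks it against `glm` and against a coarse-to-fine
grid search of the likelihood.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains generate/load → preprocess → featurize → split →
train → evaluate, writing the feature table (CSV, fixed 12-significant-
digit formatting), model (JSON), metric report (JSON), ROC curve (CSV)
and a YAML config snapshot whose MD5 is the run's config hash. One master
seed drives everything: the generator uses it directly and the stratified
70/30 split uses seed + 1, so identical configs reproduce every artifact
byte for byte (the log file, which records wall-clock timings, is
intentionally not part of that guarantee). Any stage failure aborts with
a stage-tagged message; artifacts written before the failure are left for
debugging.

The test suite and the acceptance script exercise the pipeline at 64×64
images with 100–200 samples and the default 16-kernel Gabor bank — sizes
chosen so the whole battery, including brute-force oracles, runs
comfortably on a single CPU while still being large enough for the
boosting-versus-single-stump comparison to be meaningful.

## Known limitations

- The generator's realism limits (above) bound what green tests imply
  about clinical data.
- Per-image min–max quantization discards absolute intensity calibration;
  if calibrated gray levels matter, quantize against a fixed range before
  feature extraction.
- The DWT stage requires even image dimensions per level and is
  shift-sensitive.
- Discrete AdaBoost with stumps ignores feature interactions beyond what
  boosting's reweighting captures; no probability calibration is provided
  (margins are monotone scores, not probabilities).
- The logistic stage is a generic design-matrix fit; it does not select
  covariates.
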