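# sonotex

Texture-based computer-aided classification of thyroid nodules in B-mode
ultrasound images.

Radiologists grade thyroid nodules as benign or malignant from subtle
sonographic texture cues, a judgement that is subjective and
experience-dependent. `sonotex` implements a complete, tested CAD pipeline
for this two-class problem: speckle-aware preprocessing, second-order
texture and wavelet-energy features, and a boosted decision-stump
classifier, together with the evaluation statistics a diagnostic study
reports. Because clinical ultrasound archives are rarely shareable, the
package ships a synthetic speckle-texture generator that emulates the
two-class setting, so every stage — and the pipeline end to end — runs and
is testable from a clean install with no data downloads.

It is aimed at researchers prototyping texture-based CAD methods and at
readers who want a transparent, from-first-principles reference
implementation of this classical pipeline.

## The method

1. **Hybrid Wiener–Gabor preprocessing.** Each image is denoised with a
   local-statistics Wiener filter,
   `out = μ + max(σ² − σ²_noise, 0)/σ² · (x − μ)` over a 3×3 window, then
   texture is enhanced with a Gabor bank (frequencies
   F ∈ {0.1, 0.2, 0.3, 0.4} cycles/pixel × orientations
   θ ∈ {0, π/4, π/2, 3π/4}), combining per-pixel maximum response
   magnitudes and rescaling to [0, 1].
2. **Co-occurrence texture features.** The gray-level co-occurrence matrix
   P(q, z) counts quantized gray-level pairs (L = 32 levels) at the four
   offsets sweeping 180° at distance Δ = 1. Ten statistics are extracted —
   autocorrelation, contrast Σ(q−z)²P, correlation, cluster prominence,
   cluster shade, dissimilarity, energy ΣP², entropy −ΣP log₂P,
   homogeneity ΣP/(1+(q−z)²), maximum probability — and averaged over the
   four offsets, which makes the vector exactly invariant to 90° rotations.
3. **Wavelet subband energies.** A periodized orthonormal 2-D wavelet
   decomposition (db2 by default) yields per-level normalized energy
   shares of the LL/LH/HL/HH subbands, appended to the feature vector.
4. **AdaBoost.** Decision stumps are boosted for T = 50 rounds with the
   classical reweighting β_t = ε_t/(1−ε_t); the strong classifier is the
   weighted-majority rule H(x) = 1 iff Σ_t log(1/β_t) h_t(x) ≥
   ½ Σ_t log(1/β_t), whose margin doubles as the ROC score.
5. **Evaluation.** Accuracy (tp+tn)/(tp+tn+fp+fn), sensitivity tp/(tp+fn),
   specificity tn/(tn+fp), ROC/AUC (trapezoidal, equal to the Mann–Whitney
   pair probability with half credit for ties), and logistic multiple
   regression (IRLS with Wald tests) for risk-factor analysis.

## Worked example

```r
library(sonotex)

config <- pipeline_config(
  synthetic = synthetic_config(n_benign = 30, n_malignant = 70),
  rounds = 50, seed = 7
)
record <- run_pipeline(config, out_dir = "demo_run")
record$report
#> accuracy 86.7%, sensitivity 90.5%, specificity 77.8%
#> AUC 0.958
```

The run generates 100 synthetic 64×64 nodule images (30 benign, 70
malignant), extracts 14 features per image (10 co-occurrence + 4 wavelet
energies), trains on a stratified 70% split and evaluates on the held-out
30 images: of 21 malignant test images 19 are detected (2 false
negatives), of 9 benign images 7 are correctly rejected, and the margin
scores rank a random malignant image above a random benign one 95.8% of
the time. `demo_run/` now holds the feature table, the serialized model,
the metric report, the ROC curve and the config snapshot; rerunning with
the same config reproduces them byte for byte.

Single images can be processed directly:

```r
ds <- generate_dataset(synthetic_config(n_benign = 1, n_malignant = 1, seed = 7))
extract_fglcm(hwgf_preprocess(ds$images[[2]]))
#>       AC         CT         CR         CP         CS          D         EN
#> 160.7872     2.6825     0.9409 23866.8381   341.5765     1.2032     0.0124
#>       ET          H         MP
#>   6.8385     0.5340     0.0294
```

A command-line wrapper with `simulate`, `featurize`, `train`, `predict`,
`evaluate` and `run` subcommands is installed at
`system.file("cli", "sonotex", package = "sonotex")`.

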