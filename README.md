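# sodiumSR

Physics-informed super-resolution for sodium (²³Na) brain MRI in R.

Sodium MRI carries biologically meaningful contrast in brain tumors —
tissue sodium rises with proliferation, altered ion transport (notably the
sodium–proton exchanger NHE1) and necrosis — but the ²³Na signal is four
orders of magnitude weaker than ¹H, so clinical 3T acquisitions are coarse
(≈5.5 mm isotropic) and noisy. `sodiumSR` implements an anatomically
constrained conditional GAN that maps a native low-resolution sodium
volume, together with a Canny edge prior extracted from the co-registered
post-contrast T1-weighted scan, to a 1 mm isotropic synthetic sodium
volume, plus everything needed to train and validate such a model without
patient data:

- **Artifact simulator** — physics-based k-space degradations used to build
  paired training data: B0 susceptibility-driven geometric distortion,
  chemical shift of the fat component (430 Hz fat–water offset at 3T),
  Nyquist (N/2) ghosting from alternating-line modulation, Gibbs ringing /
  downsampling by k-space truncation, and Rician magnitude noise
  (`composeDegradation()` and the individual operators).
- **Digital phantom** — a parametric head with nested tumor compartments
  (necrosis ⊂ contrast-enhancing tumor ⊂ T2-hyperintense lesion), NAWM
  reference, 5 mm vitreous (eye) spheres and a scalp fat ring, with paired
  high-/low-resolution sodium acquisitions (`generateHeadPhantom()`).
- **Networks** — an attention recurrent-residual U-Net generator and a 3D
  PatchGAN discriminator (3×3×3 kernels, stride 2, padding 1, 4 layers;
  effective receptive field 31 × 31 × 16 on 16-slice inputs), trained with
  binary cross-entropy + L1 at a 1:200 weighting by a stacked
  transfer-learning curriculum of increasingly complex artifacts
  (`buildGenerator()`, `buildDiscriminator()`, `runCurriculum()`). The 3D
  convolutions, reverse-mode autodiff and Adam optimizer are implemented
  in-package (BLAS-backed, deterministic, single-threaded).
- **Inference** — pre-upsampling to the anatomical grid, overlapping-patch
  tiling with raised-cosine blending, intensity rescaling
  (`enhanceVolume()`, `tileAndStitch()`).
- **Evaluation** — vitreous-humor normalization, lesion and NAWM SNR,
  per-VOI statistics, Pearson/Spearman/paired-t comparisons, ordinal NHE1
  grading (0 / ≤33 / ≤66 / ≤100 % positive cells), and cohort summaries
  (`vitreousNormalize()`, `computeSNR()`, `compareNativeSynthetic()`,
  `nhe1Grade()`, `cohortSummary()`).

Volumes are S4 `ImageVolume`/`MaskVolume` objects (3D array + spacing +
origin) with NIfTI-1 I/O via RNifti.

## Worked example

Train a small curriculum on generated phantoms and enhance a held-out
phantom (a few minutes on one CPU):

```r
library(sodiumSR)

sampler <- defaultSpecSampler(shape = c(24L, 24L, 8L),
                              spacing = c(2.5, 2.5, 4))
stages <- list(
  CurriculumStage("noise", "rician", epochs = 15,
                  learningRate = 1e-3, init = "fresh"),
  CurriculumStage("noise+gibbs", c("gibbs_downsample", "rician"),
                  epochs = 15, learningRate = 1e-3))
bundle <- runCurriculum(stages, function(stage, s)
  makeTrainingPairs(20, sampler, curriculumStage = stage, seed = s),
  seed = 1,
  bundle = newModelBundle(GeneratorConfig(depth = 2, baseWidth = 6,
                                          recurrence = 1),
                          DiscriminatorConfig(nLayers = 3, baseWidth = 4),
                          seed = 1))

ph  <- generateHeadPhantom(sampler(deriveSeed(1, 9001L)))
deg <- resampleToGrid(ph@loResSodium, voxelSpacing(ph@hiResSodium))
enh <- enhanceVolume(ph@loResSodium, ph@t1Post, bundle,
                     targetSpacing = voxelSpacing(ph@hiResSodium))
nawm <- ph@masks$NAWM
cat("NAWM SNR native:", computeSNR(deg, nawm, nawm),
    " synthetic:", computeSNR(enh, nawm, nawm), "\n")
cat("L1 native:", mean(abs(volData(deg) - volData(ph@hiResSodium))),
    " synthetic:", mean(abs(volData(enh) - volData(ph@hiResSodium))), "\n")
```

On this seed the run prints

```
NAWM SNR native: 16.61325  synthetic: 20.75557
L1 native: 10.54278  synthetic: 5.722927
```

i.e. the enhanced phantom is both closer to the noiseless ground truth
(mean absolute error 5.7 vs 10.5 signal units) and cleaner within
normal-appearing white matter (SNR 20.8 vs 16.6).

A command-line entry point with `phantom`, `simulate`, `train`, `enhance`
and `evaluate` subcommands is installed at
`system.file("scripts", "sodiumsr", package = "sodiumSR")` (see
`runCli()`).

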