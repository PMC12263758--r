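---
title: "Methods: physics-informed super-resolution of sodium MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physics-informed super-resolution of sodium MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sodium (²³Na) MRI of the brain reports tissue sodium concentration, which
rises in tumors with cellular proliferation, upregulated sodium–proton
exchange (NHE1), extracellular-matrix reorganization and necrosis. The
sodium signal at 3T is so weak that clinical acquisitions trade resolution
for signal: typical voxels are 5.5 mm isotropic against ~1 mm for proton
anatomy, and the images are noisy. `sodiumSR` implements a
super-resolution strategy for this setting: a conditional GAN that learns,
from synthetically degraded image pairs, to undo the characteristic
physics of the degradations, constrained by anatomical edges from the
co-registered post-contrast T1-weighted scan so that structure is moved
only where anatomy supports it.

This vignette documents the model, its assumptions, the tunable
parameters, the synthetic data generator, the numerical choices, and the
limits of what the packaged tests demonstrate.

## Degradation model

Training pairs are built by degrading clean volumes with up to five
physics-based operators, composed in a fixed canonical order:

1. **B0 geometric distortion** (`applyB0Distortion`). Off-resonance
   `Δf(x)` displaces signal along the phase-encode axis by
   `Δf / BW` voxels, where `BW` is the per-voxel bandwidth. The warp is a
   per-line 1D inverse mapping with linear interpolation; an optional
   Jacobian factor `1 − d′(y)` conserves integrated line signal (verified
   to 1% on linear fields). Uniform fields reduce to rigid translations.
2. **Chemical shift** (`applyChemicalShift`). The fat-masked component is
   translated by `Δf_fat−water / BW` voxels (430 Hz at 3T; at 86 Hz/px
   exactly 5 voxels) and re-added to the water component. Because the
   simulator works on magnitude images with no spectral information, fat
   is identified by a mask.
3. **Nyquist ghost** (`applyNyquistGhost`). Alternating phase-encode
   k-space lines are modulated by `g·exp(iφ)`. The modulation depends only
   on the phase-encode frequency index, so it is applied through a 1D DFT
   along that axis; `φ = π` relocates the image by half the field of view,
   the extreme N/2 ghost.
4. **Gibbs ringing / downsampling** (`applyGibbsTruncation`). k-space is
   truncated to a centred window per axis (ringing); optionally the grid
   is cropped (resolution loss), with spacing rescaled so physical extent
   is preserved and the DC term rescaled so mean intensity is conserved.
   One operator produces both effects because they are the same physics:
   finite k-space support.
5. **Rician noise** (`addRicianNoise`). Magnitude reconstruction of a
   complex signal with i.i.d. Gaussian noise in both channels:
   `M = sqrt((S + n₁)² + n₂²)`. Zero-signal voxels are Rayleigh
   (mean `σ√(π/2)`); in general `E[M²] = S² + 2σ²`. These closed forms are
   the package's Monte-Carlo test oracles.

Noise is applied last because it arises at reconstruction, after every
geometric and sampling effect; geometry precedes k-space effects because
susceptibility and chemical shift act on the object, truncation on its
acquisition. Edge handling for all geometric shifts is zero-fill (signal
does not wrap), and every operator at its null parameters is the identity.

The off-resonance field for stage 1 is synthesized
(`synthesizeFieldMap`) as a random low-order polynomial plus
Gaussian-smoothed noise, rescaled to a peak magnitude between 60% and
100% of a configured amplitude. This is a declared stand-in: detailed
susceptibility modelling from tissue maps is out of scope.

## Networks and objective

The generator is an attention R2U-Net: a U-Net whose convolution blocks
are recurrent-residual (each 3×3×3 convolution applied `t` times with
shared weights around a 1×1×1 shortcut) and whose skip connections pass
through attention gates (a sigmoid gate computed from the upsampled
decoder signal and the skip features). It is shape-preserving — input
extents must be divisible by `2^(depth−1)` — so super-resolution enters
through the grid: the sodium volume is resampled to the 1 mm anatomical
grid *before* the network. Inputs are 2-channel (percentile-normalized
image + binary Canny edge prior); the output is 1-channel and linear, with
clipping to the non-negative range done at post-processing.

The discriminator is a 3D PatchGAN: four convolutional layers with 3×3×3
kernels, stride 2, padding 1, judging overlapping patches rather than
whole volumes. Its theoretical receptive field per axis is
`RFₙ = RFₙ₋₁ + (k−1)·∏ strides below`, i.e. 31 voxels after four layers;
a 16-slice input clips the through-plane extent, giving the effective
31 × 31 × 16 patch. `receptiveField()` implements the closed form and
`receptiveFieldOracle()` confirms it by measuring the gradient support of
a central output logit on an instantiated network. It conditions on the
(degraded input, candidate output) channel pair, standard conditional-GAN
practice.

The generator objective is binary cross-entropy against the real label on
the discriminator's patch logits plus an L1 reconstruction term, weighted
1:200; the discriminator minimizes the mean BCE of real/fake patch
logits. Optimization is Adam (β = 0.9/0.999), default learning rate 1e-4,
constant schedule.

Because no deep-learning framework is available to R in this environment
class, the package carries its own small engine: tape-based reverse-mode
autodiff over 4D feature maps with im2col (BLAS) 3D convolutions, max
pooling, nearest upsampling, attention gating and the two losses. It is
deterministic given seeds, and every layer's gradient is
finite-difference tested.

### Stacked transfer learning

Training proceeds through an ordered curriculum of stages with
non-decreasing artifact complexity (`runCurriculum`); each stage after
the first initializes from the previous stage's weights. The default
order adds noise first, then Gibbs/downsampling, then ghosting, chemical
shift and B0 — noise-to-geometry, easiest to hardest; the order is
config-driven. "16-slice" processing is interpreted as the patch depth
(training samples are up-to-256×256×16 sub-volumes), the reading
consistent with the 31 × 31 × 16 receptive field.

## Synthetic data

`generateHeadPhantom()` builds an analytic head: a head ellipsoid with a
scalp fat ring (present solely so the chemical-shift operator acts
nontrivially), a brain ellipsoid, two vitreous spheres (5 mm diameter, the
clinical eye-VOI convention), a nested spherical lesion
(necrosis ⊆ enhancing tumor ⊆ T2-hyperintense), and a contralateral NAWM
reference sphere. Two channels are painted from per-compartment means: a
sodium channel (brain/NAWM 100 arbitrary units; vitreous 250; lesion
compartments at `sodiumLesionRatio` × brain, 1.4 by default, shared
across the three compartments so the whole-lesion:NAWM ratio equals the
spec'd value exactly) and a T1-like anatomical channel (enhancing rim
bright, necrotic core dark, fat bright). The native acquisition is
simulated by k-space downsampling to 5.5 mm isotropic (the closest
integer grid) plus Rician noise.

Analytic geometry means every mean, volume and SNR has a closed form the
tests check exactly. What the phantom does *not* emulate: anatomical
texture, vasculature, partial-volume transition zones, contrast-agent
kinetics, coil shading. Passing tests therefore demonstrate that the
pipeline recovers piecewise-smooth structure under the modelled
degradations — not clinical performance on real scans, which requires the
original cohort.

## Anatomical prior

Edges are extracted per axial slice with a 2D Canny detector
(`cannyEdgeVolume`): Gaussian smoothing (σ = 1 voxel), Sobel gradients,
non-maximum suppression along the quantized gradient direction, and
double-threshold hysteresis (0.1/0.2 on the percentile-normalized [0, 1]
scale). The source names the algorithm but not its parameters or
dimensionality; 2D slice-wise matches the 16-slice patch processing and
the defaults are declared, not inferred. Two implementation details are
deliberate: the one-pixel image border is suppressed (zero-fill shifts
would otherwise mark the frame as edge), and plateau ties break toward
one side so a step edge is exactly one voxel thick.

## Inference

`enhanceVolume()` resamples the native sodium volume to the anatomical
grid (trilinear; masks would use nearest-neighbour with re-binarization),
normalizes by the 99th-percentile divisor, concatenates the edge channel,
tiles into patches (default 256×256×16, shrunk to fit small volumes),
runs the generator, and stitches with a separable raised-cosine window
whose accumulated weights are normalized to one at every voxel — so an
identity generator reproduces the input exactly, a property the tests
assert. Outputs are clipped non-negative and rescaled through the input's
normalization divisor, so downstream vitreous normalization is
well-defined. Volumes smaller than a patch are reflection-padded and
cropped back.

## Evaluation protocol

Per case: divide native and synthetic volumes by the mean intensity over
the pooled left+right eye VOIs (`vitreousNormalize`; per-eye means are
also reported), compute normalized means over the enhancing, necrotic and
T2-hyperintense compartments, and two SNRs — lesion SNR
(T2-hyperintense mean over NAWM standard deviation) and NAWM SNR (NAWM
mean over its own standard deviation). Cohort level:
Pearson r/r²/slope with 95% CI (least squares), Spearman ρ, two-sided
paired t; sample (n−1) standard deviations throughout; p < 0.05 taken as
significant by convention. NHE1 immunohistochemistry is graded ordinally
from percent positive cells — 0: none; 1: (0, 33]; 2: (33, 66];
3: (66, 100] — with boundary values assigned to the lower grade ("up to"
read inclusively) and any nonzero grade flagged as elevated. Degenerate
inputs are handled explicitly: zero-variance vectors raise a domain error
for correlations, and a paired t on zero-variance differences reports the
zero mean difference with an undefined-p flag rather than NaN.

## Numerical and design choices

- **Coordinates**: 0-based voxel indices, physical position
  `origin + index · spacing`, axis order (x, y, z); no orientation matrix
  beyond axis flips. One fixed convention keeps every oracle exact.
- **Percentile normalization** uses the order-statistic (type-1)
  percentile and clips to [0, 1]; scale-invariant and robust to the
  vitreous/lesion tail.
- **Resampling** chooses the output grid as
  `round(extent / target spacing)`, preserving physical extent (48³ at
  5.5 mm → 264³ at 1 mm); masks are nearest-neighbour + re-binarized at
  0.5 to preserve nesting.
- **k-space windows** are centred on DC (DC always kept), so constant
  volumes and mean intensity survive truncation and downsampling.
- **Initialization**: He-uniform convolutions, zero biases, and a
  zero-initialized final 1×1 projection so training starts from a neutral
  output under the heavily L1-weighted objective.
- **Determinism**: a single seed expands into per-module seeds via a
  counter-based mix (`deriveSeed`); all operators, training and inference
  are bit-reproducible given (inputs, config, seed) on a fixed BLAS.
- **Recurrence `t = 2` and base width 32** are the full-size generator
  defaults; both are config-exposed since the source geometry is not
  fully specified.

### Scaled study sizes

The packaged tests and examples run the whole pipeline at reduced sizes
chosen once as this package's scaled study conditions: training phantoms
of 24 × 24 × 8 voxels at (2.5, 2.5, 4) mm, 20 training pairs per stage, a
depth-2/width-6/t = 1 generator against a 3-layer/width-4 discriminator,
and a two-stage curriculum (Rician noise, 15 epochs → + Gibbs/
downsampling, 15 epochs) at learning rate 1e-3 — a rate suited to these
few-step runs, where the full-size default 1e-4 would barely move the
weights. Under these conditions the curriculum reliably improves both the
reconstruction L1 against ground truth and the NAWM SNR of enhanced
versus degraded phantoms (median over 3 seeds), which is what the
acceptance suite asserts.

## Known limitations

- The clinical headline numbers of the motivating study (cohort SNR
  gains, native–synthetic R² per compartment, the NHE1 association)
  depend on a 20-patient validation cohort and cannot be reproduced from
  synthetic data; the package reproduces the *protocol*, and its cohort
  summary reproduces the published demographics table exactly.
- The susceptibility field generator is a declared stand-in, not a
  tissue-based model.
- Inputs are assumed co-registered (checked only by field-of-view
  agreement); registration is out of scope.
- The pure-R training engine is practical at phantom scale; full-size
  (256×256×128) training is architecturally supported but
  computationally out of reach without a GPU framework.
- An ambiguity in the source is surfaced, not resolved: the same
  synthetic–NHE1 association value is labelled ρ in one place and R² in
  another; `compareNativeSynthetic` returns both statistics explicitly
  and leaves interpretation to the user.
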