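---
title: "Simulating and detecting cone photoreceptors in confocal AOSLO images"
author: "coneUNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting cone photoreceptors in confocal AOSLO images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coneUNet)
```

## The problem

Adaptive optics scanning laser ophthalmoscopy (AOSLO) resolves individual
cone photoreceptors in the living retina. Quantitative analysis — density,
spacing, per-cell reflectance — starts from the positions of individual
cones, which are traditionally marked by hand. `coneUNet` implements a
fully automated alternative: a convolutional encoder-decoder network is
trained to regress a cone-probability map from a confocal AOSLO image, and
discrete cone centres are extracted from that map by thresholded peak
detection. Because annotated real images are scarce, the network is trained
on synthetic images of the cone mosaic with exact ground truth, generated
by the package itself; transfer learning then adapts the network to real
instruments using a comparatively small annotated set.

This vignette documents the models behind each stage, the parameters that
matter, the numerical choices, and what the shipped tests do and do not
demonstrate.

## Synthetic cone mosaics

`generateMosaic()` places cone centres on a hexagonal lattice whose
centre-to-centre spacing follows a linear model of retinal eccentricity,
`s(e) = s0 + k e`, with defaults `s0 = 4` µm and `k = 0.6` µm/deg. The
defaults approximate published histology trends: about 4.6 µm at 1° rising
to 10 µm at 10°. The lattice receives isotropic Gaussian positional jitter
and any pair closer than half a spacing is pruned, so cones never merge.
Cone diameter is fixed at 0.8 × spacing, and each cone draws an
independent log-normal relative reflectivity (median 1, `sdlog` 0.35) so
every simulated retina has a different reflectance pattern.

Two of these choices deserve comment:

* **Jitter amplitude.** The generator targets a quasi-hexagonal mosaic
  whose mean nearest-neighbour distance stays within 10% of the spacing
  model. Jitter with sd 0.1 × spacing pulls the mean nearest-neighbour
  distance about 17% below the lattice spacing (the minimum over six
  neighbours is biased low), so the default is `jitterFrac = 0.05`, which
  keeps the deviation near 9% while still breaking the perfect lattice.
* **Reflectivity distribution.** Only the *variability* of reflectance
  across cones matters downstream (it modulates image contrast); the
  log-normal shape is a convenience choice, configurable via `sdlog`.

`renderScene()` draws each cone as a radially symmetric Gaussian of FWHM
equal to the cone diameter, truncated at one diameter, scaled by its
reflectivity. Profiles add linearly, so the rendered scene is linear in
reflectivity and its total flux equals the sum of per-cone integrals — both
properties are asserted by tests.

## Optics: diffraction and residual aberrations

`psfFromWavefront()` renders point spread functions by Fourier optics: a
circular pupil (default 5 mm) carries the phase `2π/λ × a W(ρ, θ)`, where
`W` is built from OSA/ANSI-indexed Zernike coefficients in microns and `a`
is the *amplitude fraction* — the proportion of the measured aberration
retained after adaptive-optics correction (study grid: 0.1, 0.2, 0.3).
Piston, tip and tilt are excluded from the phase: they shift but do not
blur. Pupil-plane angles are converted to retinal microns through a
reduced-eye focal length (default 17 mm, ≈ 291 µm/deg). With a zero
wavefront the result is the Airy pattern; the first-minimum radius matches
`1.22 λ/D` to better than 1% in the shipped tests, and kernels are always
non-negative with unit sum (energy conservation after the documented crop,
which retains all but `1e-4` of the energy).

Aberration inputs are per-eye Zernike time series. `meanZernikeOverTime()`
averages each mode over time; `selectLowestRmsEyes()` ranks eyes by total
RMS wavefront error (the Euclidean norm of the unit-RMS-normalised
coefficients, modes j ≥ 3). Because no measured series ships with the
package, `syntheticZernikeSeries()` generates a clearly-labelled synthetic
panel whose per-mode amplitudes fall off with radial order as `1/n²`, a
crude match to the declining power of higher-order ocular aberrations;
measured CSVs in the same long format can be substituted directly.

Scenes are blurred by `applyOptics()` — linear convolution with reflect
padding (avoids dark frame edges inside training crops), verified against
a direct spatial-domain oracle.

## Acquisition: signal, noise, frame averaging

`setSignal()` rescales a scene so its mean equals the configured pinhole
power (nW) times a detector calibration (default 1000 units/nW).
`simulateFrame()` adds i.i.d. Gaussian white noise (clipping negative
detector values at zero) and `averageFrames()` takes the pixel-wise mean of
N frames, as AOSLO practice does — without registration, since no eye
motion is simulated. The default noise sd (240 units) was chosen once so
the central study condition (0.30 nW, 20 frames) lands near 15 dB SNR,
`SNR = 20 log10(mean / (σ/√N))` being the package's documented definition.
The √N noise-reduction law is exercised in a clipping-free regime (bright
uniform scene) because zero-clipping on dark backgrounds deflates the
residual sd — the law is a property of the averaging operator, not of the
clipping.

## Labels, tiling, augmentation, manifest

Training targets are Gaussian heatmaps (`makeLabelMap()`): each cone centre
contributes an isotropic Gaussian of sd `coneWidthPx/4`, truncated at one
cone radius, combined across cones by maximum-intensity projection (never
summed, so touching cones keep distinct peaks), normalised to [0, 255].
The σ default is a design choice (the heatmap recipe leaves it open); the
truncation-at-one-diameter and max-projection rules are structural.

Full 480 × 300 images are tiled (`tileImage()`) into 4 × 3 equal tiles of
120 × 100, each centre-cropped to 96 × 96 — twelve pairwise-disjoint crops
whose coordinates round-trip exactly. (480 × 300 does not tile into twelve
96 × 96 squares exactly; the centre-crop construction honours both the
twelve-crop count and the 96 × 96 input size.) `augmentCrop()` enumerates
(rotation, x-axis-flip) pairs — a 200-fold augmentation is 100 evenly
spaced angles × 2 flip states — applying the identical transform to image,
label and centres; rotations resample bilinearly with reflect fill.

`buildManifest()` enumerates the full synthetic study: three condition
sets (noise: 4 signal levels × 3 frame counts; residual aberration: 4 eyes
× 3 amplitude fractions; combined: 10 eyes) × 19 eccentricities × 100
images × 12 crops = 775,200 crop records, split 60/20/20 stratified by
condition and eccentricity. For real data `buildRealManifest()` assigns
splits at the (participant, eccentricity) group level so no group leaks
across splits.

## The network

`buildNetwork()` constructs a symmetric encoder-decoder with multi-scale
modules: parallel branches of stacked 3 × 3 convolutions (1, 2, 3 convs ≈
3 × 3, 5 × 5, 7 × 7 receptive fields), concatenated, fused by a 1 × 1
convolution, with a 1 × 1-projected residual shortcut added before the
module's batch-norm (always before the ReLU). The parallel branches let
the network track cone width, which varies with eccentricity and pixel
scale. Levels communicate by 2 × 2 stride-2 max pooling down and
nearest-neighbour upsampling + 1 × 1 channel reduction up, with skip
concatenation from the matching encoder level; a final 1 × 1 convolution
regresses the single-channel probability map. All convolutions zero-pad,
so predictions keep the 96 × 96 input size. Weights initialise from random
orthogonal matrices.

The full-size defaults — depth 4, filters 16/32/64/128, bottleneck 392 —
give 8,915,649 trainable parameters (≈ 8.9 M). Published figures leave the
per-level filter counts under-determined; these defaults were chosen once
to land at that capacity with the module structure above.
`tinyNetworkConfig()` (depth 2, base 8, branches {3, 5}, ≈ 44 k
parameters) is a first-class desk-scale configuration used by the tests.

Training (`trainNetwork()`) minimises mean-squared error against the
[0, 255] label maps with Adam (initial learning rate 1e-3; 1e-4 for
transfer learning), batch size 32. Internally the network regresses
labels/255: Adam's step size is gradient-scale-free, so matching parameter
scale to target scale is what lets desk-scale runs converge in tens of
steps; reported losses are always in [0, 255]² units, where the plateau
rules live. Validation loss drives a plateau schedule: an epoch counts as
improving only if it undercuts the best loss by ≥ 1.0 (MSE units on
[0, 255] labels); after 5 consecutive non-improving epochs the learning
rate halves (floor 1e-5), and after 7 it stops. The logic is pure and
replayable (`replayScheduler()`), pinned by tests to halve at the 6th
non-improving epoch and stop at the 8th. `assignFolds()` partitions
training groups into the 4 cross-validation folds.

Transfer learning (`fineTune()`) freezes every block except the last
expansive-path module (`dec1`, including its up-convolution) and the
output head. Frozen parameters are bit-identical before and after —
asserted bitwise — and frozen batch-norm layers also stop updating their
running statistics (the freeze would otherwise leak distribution shift
into supposedly fixed blocks).

The network, backpropagation and optimiser are implemented in the package
on RcppArmadillo: convolutions run as per-tap shifted GEMMs in single
precision (the analytic gradients are verified against finite differences
in the tests; heatmap regression is far from the float32 precision floor).

## Detection and evaluation

`detectCones()` zeroes map pixels below the intensity threshold T, finds
local maxima with a minimum separation (default half the cone width),
and refines each surviving peak to the probability-weighted centroid of
its above-threshold neighbourhood, weighting with the *raw* map values
inside the support. Plateau ties resolve by scan order and, if centroid
refinement merges two peaks, the larger-mass one is kept, so the minimum
separation is a hard invariant of the result.

`estimateConeWidth()` recovers the modal cone spacing from Yellott's ring:
the radially averaged power spectrum shows an annular peak at the
hexagonal row frequency `2/(√3 s)`. The smooth spectral envelope
(reflectivity variation, blur and noise roll-off) is removed with a
log-log smoothing spline, and the lowest-frequency prominent excess peak
is converted to spacing, then to width via the 0.8 width/spacing ratio.
On full 480 × 300 images the estimate is accurate to ~1% at all supported
eccentricities, with or without noise; on single 96 × 96 crops the ring is
statistically weak, so the pipeline estimates the width once per parent
image and shares it with the image's crops. A structureless input returns
the configured fallback width with a warning.

`matchCones()` implements the evaluation protocol: cones strictly within
χ cone widths of an image edge are excluded (a cone exactly on the margin
is retained — the documented boundary convention); candidate pairs within
χ cone widths are then scanned in globally ascending distance order
(ties by predicted then truth index) and accepted greedily one-to-one, so
each ground-truth cone pairs with its nearest available prediction. An
independently coded brute-force matcher in the tests reproduces the
pairing exactly on 200 random instances. `computeMetrics()` applies

* Dice = 2TP / (2TP + FP + FN)
* TPR = TP / (TP + FN)
* FDR = FP / (TP + FP)

with documented empty-denominator conventions (Dice 1 on fully empty
images; TPR 1 with no truth cones; FDR 0 with no predictions).
`evaluateDataset()` reports per-image metrics with mean and sample (n − 1)
SD. `tuneThresholds()` selects (T, χ) by maximising mean validation Dice,
breaking ties toward larger T then smaller χ (favouring precision);
`operatingPoint()` records the validated presets T = 120, χ = 0.75
(Milwaukee confocal set) and T = 45, χ = 0.5 (Oxford set).

## The desk-scale experiment

`runEndToEnd()` reproduces the whole pipeline at a scale a single CPU
handles in minutes, using the combined condition (0.30 nW, 20 averaged
frames, 10% residual aberration from the lowest-RMS eye): 42 images at
each of 4 eccentricities (2°, 4°, 6°, 8°) → 2,016 crops of 96 × 96, split
60/20/20. The tiny network trains for up to 16 epochs with on-the-fly dihedral
augmentation (random 90-degree rotations and x-axis flips per batch, the
exact-resampling subset of the rotation/flip augmentation family; at this
data scale it is what keeps validation loss tracking training loss), and
the scheduler
monitors a fixed random 128-crop validation subsample; the full validation split
is reserved for threshold tuning over T ∈ {15, …, 240}, χ ∈ {0.5, 0.75,
1.0}), and the held-out test crops are evaluated at the tuned operating
point with per-parent-image estimated cone widths. The acceptance suite
requires mean test Dice ≥ 0.90 from this run.

What this does and does not show: the synthetic generator emulates
diffraction, residual aberration, calibrated signal and frame-averaged
Gaussian noise over a realistic eccentricity range, but not rods, blood
vessels, retinal curvature or eye motion, and the tiny network is ~200×
smaller than the full configuration. Passing the desk-scale run therefore
demonstrates that the pipeline's machinery — simulation, labels, training,
detection, matching — is correct and self-consistent; it does not certify
performance on real AOSLO images. The published full-scale figures (mean
Dice 0.989 on the Milwaukee confocal test set; 0.962 on the Oxford set)
require the real datasets and GPU-scale training of the 8.9 M-parameter
model and are reference targets only, not outputs this package recomputes.

## Numerical choices and limitations

* PSF kernels are cropped to the smallest centred odd window holding all
  but 1e-4 of the energy, then renormalised; the Nyquist guard warns when
  the pixel scale undersamples the Airy core.
* The mosaic's pair-separation filter uses a vectorised cell list, linear
  in cone count; separation violations are astronomically rare at the
  default jitter but the guarantee is enforced regardless.
* Convolution edge handling is reflect padding everywhere (optics and
  rotation resampling alike) to avoid dark borders in crops.
* Frame noise is seeded per (config seed, frame index), so any frame can
  be regenerated in isolation; pipeline stages derive independent seeds
  from the master seed.
* `detectCones()` is exact-tie deterministic but its greedy suppression is
  order-dependent by intensity; equal-intensity peaks closer than the
  minimum distance resolve by scan order.
* Real-image ingestion (150 × 150 or 100 × 100 pixel sets) reuses the same
  crop/label machinery, but the package ships no real data; the Milwaukee
  and Oxford datasets must be obtained from their public repositories.
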