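# coneUNet

Automated cone photoreceptor detection for confocal adaptive optics
scanning laser ophthalmoscope (AOSLO) images, trained on synthetic data.

Quantitative analysis of the living cone mosaic — density, spacing,
per-cell reflectance — needs the position of every cone, and marking them
by hand is slow and subjective. `coneUNet` implements the full pipeline
for replacing manual labelling:

1. **Synthetic mosaics with exact ground truth.** Quasi-hexagonal cone
   mosaics across retinal eccentricities 1°–10° (spacing
   `s(e) = 4.0 + 0.6 e` µm, per-cone log-normal reflectance), rendered at
   1 µm/px and imaged through a Fourier-optics model: diffraction for an
   850 nm / 5 mm-pupil system, residual aberration as a scaled fraction
   (10–30%) of per-eye Zernike wavefronts, calibrated pinhole signal
   (0.20–0.35 nW) with Gaussian white noise, and 10/20/30-frame averaging.
2. **Heatmap labels.** Cone centres become Gaussian blobs truncated to one
   cone diameter, combined by maximum-intensity projection, on [0, 255].
3. **A multi-scale encoder-decoder network** (U-Net family) whose levels
   run parallel convolution branches with 3×3/5×5/7×7 receptive fields
   plus residual shortcuts; the full configuration carries ≈ 8.9 M
   trainable parameters, a `tiny` configuration (~44 k) runs on a desk
   CPU. Training: Adam on MSE, batch 32, plateau halving of the learning
   rate and early stopping on validation loss; transfer learning re-trains
   only the last expansive block.
4. **Detection.** Probability maps are thresholded at intensity `T`, peaks
   with a minimum separation are refined to probability-weighted
   centroids; cone width is estimated per image from Yellott's ring in the
   power spectrum.
5. **Evaluation.** One-to-one nearest-available matching within χ cone
   widths (edge cones excluded), then

   ```
   Dice = 2TP / (2TP + FP + FN),  TPR = TP / (TP + FN),  FDR = FP / (TP + FP)
   ```

   summarised per image with mean and SD. `(T, χ)` are tuned on
   validation data by maximising mean Dice; validated presets are
   `T = 120, χ = 0.75` (Milwaukee confocal dataset) and `T = 45, χ = 0.5`
   (Oxford dataset).

The network, backpropagation and optimiser are implemented in the package
itself on RcppArmadillo; no external deep-learning framework is required.

## Worked example

```r
library(coneUNet)

# one synthetic acquisition at 5 degrees eccentricity
mosaic <- generateMosaic(5, fieldSize = c(480L, 300L), seed = 1)
mosaic
#> ConeMosaic: 3376 cones at 5.0 deg, field 480 x 300 px (1.00 um/px), cone width 5.60 um

psf <- psfFromWavefront(wavefront(numeric(1), 0L), opticsSpec())
image <- acquireImage(applyOptics(renderScene(mosaic), psf),
                      acquisitionConfig(signalNW = 0.30, nFrames = 20L))
snr(image, acquisitionConfig())          # 15.35 dB at the default calibration

estimateConeWidth(image)                 # 5.60 px from Yellott's ring

# ground-truth heatmap label and a detection round-trip on it
label <- makeLabelMap(coneCentres(mosaic), coneWidth(mosaic),
                      shape = c(480L, 300L))
det <- detectCones(mapValues(label), threshold = 120, minDistancePx = 2.8)
m <- matchCones(coneCentres(det), coneCentres(mosaic),
                coneWidthPx = 5.6, chi = 0.75, imageShape = c(480L, 300L))
computeMetrics(m)
#> Dice 0.9998 | TPR 0.9997 | FDR 0.0000

# the desk-scale experiment: simulate ~2,000 crops, train the tiny
# network, tune (T, chi) on validation Dice, evaluate held-out crops
res <- runEndToEnd(pipelineConfig("tiny", outputDir = "cone_run", seed = 1))
res$summary
```

On the held-out synthetic test split this desk-scale run reaches a mean
Dice above 0.90 at the tuned operating point (the exact value varies
slightly with the seed). The `metric/mean/sd` table it prints reports
Dice, true positive rate and false discovery rate across test crops; the
run directory collects the training history, per-image metrics and log.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/aoslo_pipeline.R` (subcommands `simulate`, `end-to-end`,
`detect`, `evaluate`, `init-config`).

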