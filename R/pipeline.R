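#' Default pipeline configuration
#'
#' A single serialisable list drives every stage: mosaic geometry, optics,
#' acquisition grids, dataset layout, network/training settings and
#' detection/evaluation parameters. `scale = "tiny"` configures the
#' desk-scale experiment (a handful of eccentricities, tens of images, the
#' tiny network); `scale = "full"` configures the full study grid
#' (34 conditions x 19 eccentricities x 100 images x 12 crops and the
#' full-size network), which is intended for GPU-scale resources.
#'
#' @param scale `"tiny"` or `"full"`
#' @param outputDir where run artefacts are written
#' @param seed master seed; per-stage seeds are derived from it
#' @return a named list
#' @export
pipelineConfig <- function(scale = c("tiny", "full"), outputDir = "cone_run",
                           seed = 1L) {
  scale <- match.arg(scale)
  tiny <- scale == "tiny"
  list(
    scale = scale,
    output_dir = outputDir,
    seed = as.integer(seed),
    mosaic = list(field_size = c(480L, 300L), pixel_scale_um = 1.0,
                  spacing_s0 = 4.0, spacing_k = 0.6),
    optics = list(wavelength_nm = 850, pupil_diameter_mm = 5,
                  pupil_grid_size = 512L, focal_length_mm = 17),
    acquisition = list(signal_levels_nw = c(0.20, 0.25, 0.30, 0.35),
                       frame_counts = c(10L, 20L, 30L),
                       noise_sigma = 240, noise_mean = 0,
                       units_per_nw = 1000),
    aberration = list(n_eyes_aberration = 4L, n_eyes_combined = 10L,
                      fractions = c(0.1, 0.2, 0.3),
                      combined_fraction = 0.1,
                      combined_signal_nw = 0.30, combined_frames = 20L),
    dataset = list(
      eccentricities = if (tiny) c(2, 4, 6, 8) else seq(1, 10, by = 0.5),
      images_per_condition = if (tiny) 2L else 100L,
      crops_per_image = 12L, crop_size = 96L, grid = c(4L, 3L),
      split_fractions = c(train = 0.6, val = 0.2, test = 0.2)),
    network = list(tiny = tiny, epochs = if (tiny) 16L else 100L,
                   batch_size = 32L),
    detection = list(t_grid = seq(15, 240, by = 15),
                     chi_grid = c(0.5, 0.75, 1.0),
                     min_distance_factor = 0.5,
                     fallback_width_px = 6),
    end_to_end = list(images_per_ecc = if (tiny) 42L else 100L)
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips through serialisation without loss.
#'
#' @param config list from [pipelineConfig()]
#' @param path YAML file path
#' @return `writePipelineConfig`: the path invisibly;
#'   `readPipelineConfig`: the configuration list
#' @export
writePipelineConfig <- function(config, path) {
  # yaml drops vector names: store the split fractions as a map
  config$dataset$split_fractions <- as.list(config$dataset$split_fractions)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml scalarises length-1 vectors; restore known integer fields
  cfg$seed <- as.integer(cfg$seed)
  cfg$dataset$split_fractions <- unlist(cfg$dataset$split_fractions)
  cfg
}

# Simulate one full-field synthetic image for a manifest condition.
# Returns list(image, mosaic); image is the averaged acquisition (noise
# sets), the blurred scene (aberration-only sets), or both effects
# (combined).
simulateConditionImage <- function(cond, eccentricity, imageIndex, config,
                                   wavefronts, optics) {
  ms <- config$mosaic
  seed <- childSeed(config$seed, paste0(cond$condition, eccentricity),
                    imageIndex)
  mosaic <- generateMosaic(eccentricity,
                           fieldSize = ms$field_size, seed = seed,
                           pixelScale = ms$pixel_scale_um,
                           s0 = ms$spacing_s0, k = ms$spacing_k)
  scene <- renderScene(mosaic)
  wf <- if (!is.na(cond$eye) && !is.null(wavefronts[[cond$eye]]))
    setAmplitudeFraction(wavefronts[[cond$eye]], cond$fraction)
  else wavefront(numeric(1), 0L)    # diffraction only
  psf <- psfFromWavefront(wf, optics)
  blurred <- applyOptics(scene, psf, psf@pixelScaleUm)
  blurred[blurred < 0] <- 0
  img <- if (!is.na(cond$signal_nW)) {
    acq <- acquisitionConfig(signalNW = cond$signal_nW,
                             noiseSigma = config$acquisition$noise_sigma,
                             noiseMean = config$acquisition$noise_mean,
                             nFrames = cond$n_frames,
                             unitsPerNW = config$acquisition$units_per_nw,
                             seed = seed)
    acquireImage(blurred, acq)
  } else blurred
  list(image = img, mosaic = mosaic)
}

#' Simulate the synthetic image sets of a configuration
#'
#' Generates the three condition sets (noise, residual aberration,
#' combined) at the configured scale, writing averaged images (8-bit PNG),
#' float scenes are not retained. Ground-truth centre CSVs and the dataset
#' manifest CSV accompany the images. Rerunning with the same seed
#' reproduces every artefact bit for bit.
#'
#' @param config list from [pipelineConfig()]
#' @param writeImages write PNG images (ground truth and manifest are
#'   always written)
#' @return the manifest data.frame, invisibly
#' @export
runSimulate <- function(config = pipelineConfig(), writeImages = TRUE) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  imgDir <- file.path(config$output_dir, "images")
  gtDir <- file.path(config$output_dir, "ground_truth")
  dir.create(imgDir, showWarnings = FALSE)
  dir.create(gtDir, showWarnings = FALSE)

  ab <- config$aberration
  conds <- conditionGrid(
    signalLevels = config$acquisition$signal_levels_nw,
    frameCounts = config$acquisition$frame_counts,
    aberrationEyes = ab$n_eyes_aberration,
    aberrationFractions = ab$fractions,
    combinedEyes = ab$n_eyes_combined,
    combinedSignalNW = ab$combined_signal_nw,
    combinedFrames = ab$combined_frames,
    combinedFraction = ab$combined_fraction)
  manifest <- buildManifest(
    conds, eccentricities = config$dataset$eccentricities,
    imagesPerCondition = config$dataset$images_per_condition,
    cropsPerImage = config$dataset$crops_per_image,
    splitFractions = config$dataset$split_fractions,
    seed = childSeed(config$seed, "manifest"))
  utils::write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
                   row.names = FALSE)

  series <- syntheticZernikeSeries(
    nEyes = ab$n_eyes_combined, seed = childSeed(config$seed, "zernike"))
  wavefronts <- wavefrontsFromSeries(series)
  op <- config$optics
  optics <- opticsSpec(op$wavelength_nm, op$pupil_diameter_mm,
                       config$mosaic$pixel_scale_um, op$pupil_grid_size,
                       op$focal_length_mm)

  imgs <- unique(manifest[, c("image_id", "condition", "eccentricity_deg",
                              "image_index", "signal_nW", "n_frames", "eye",
                              "fraction")])
  for (i in seq_len(nrow(imgs))) {
    row <- imgs[i, ]
    sim <- simulateConditionImage(row, row$eccentricity_deg,
                                  row$image_index, config, wavefronts,
                                  optics)
    writeGroundTruth(sim$mosaic,
                     file.path(gtDir, paste0(row$image_id, ".csv")))
    if (writeImages)
      writeImage8bit(sim$image,
                     file.path(imgDir, paste0(row$image_id, ".png")))
  }
  invisible(manifest)
}

# Build label-paired 96x96 crops for a set of simulated images. Labels use
# the generator's exact cone width; the evaluation-time width attached to
# each crop is estimated from the parent image's power spectrum, as the
# evaluation protocol never consults the generator.
imagesToCrops <- function(sims, config) {
  ds <- config$dataset
  out <- list()
  for (s in sims) {
    centresPx <- coneCentres(s$mosaic) / s$mosaic@pixelScale
    widthPx <- coneWidth(s$mosaic) / s$mosaic@pixelScale
    lab <- makeLabelMap(centresPx, widthPx,
                        shape = dim(s$image)[c(2L, 1L)])
    estWidth <- suppressWarnings(estimateConeWidth(
      s$image, config$mosaic$pixel_scale_um,
      fallbackWidthPx = config$detection$fallback_width_px))
    crops <- tileImage(s$image, centres = centresPx, label = lab,
                       grid = ds$grid, cropSize = ds$crop_size)
    for (cr in crops) {
      cr$eccentricity <- s$mosaic@eccentricity
      cr$coneWidthPx <- estWidth
      out[[length(out) + 1L]] <- cr
    }
  }
  out
}

#' Run the scaled-down experiment end to end
#'
#' Simulates combined-condition images (noise + residual aberration) over
#' the configured eccentricities, builds Gaussian labels and 96 x 96 crops,
#' trains the configured network on the training split, tunes (T, chi) on
#' the validation split by maximising mean Dice, and evaluates the
#' held-out test split. Writes per-image and summary metrics CSVs plus a
#' log to the output directory.
#'
#' @param config list from [pipelineConfig()]
#' @param verbose print stage progress
#' @return list with `tuned` (T, chi), `metrics` (per-image data.frame),
#'   `summary`, `model` and `history`
#' @export
runEndToEnd <- function(config = pipelineConfig(), verbose = FALSE) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$output_dir, "run.log")
  logLine <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = logFile,
        append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  cfgStr <- paste(unlist(config), collapse = "|")
  logLine("config hash: %08x", sum(utf8ToInt(cfgStr) * seq_along(utf8ToInt(cfgStr))) %% 4294967291)

  ab <- config$aberration
  op <- config$optics
  optics <- opticsSpec(op$wavelength_nm, op$pupil_diameter_mm,
                       config$mosaic$pixel_scale_um, op$pupil_grid_size,
                       op$focal_length_mm)
  series <- syntheticZernikeSeries(
    nEyes = ab$n_eyes_combined, seed = childSeed(config$seed, "zernike"))
  eyes <- selectLowestRmsEyes(wavefrontsFromSeries(series), 1L)
  cond <- data.frame(condition = "comb", signal_nW = ab$combined_signal_nw,
                     n_frames = ab$combined_frames,
                     eye = eyes[[1L]]@eyeId, fraction = ab$combined_fraction)
  wavefronts <- stats::setNames(eyes, eyes[[1L]]@eyeId)

  logLine("simulating %d images x %d eccentricities",
          config$end_to_end$images_per_ecc,
          length(config$dataset$eccentricities))
  sims <- list()
  for (ecc in config$dataset$eccentricities)
    for (i in seq_len(config$end_to_end$images_per_ecc))
      sims[[length(sims) + 1L]] <-
        simulateConditionImage(cond, ecc, i, config, wavefronts, optics)

  crops <- imagesToCrops(sims, config)
  n <- length(crops)
  logLine("built %d crops", n)
  fr <- config$dataset$split_fractions
  split <- withSeed(childSeed(config$seed, "split"), {
    sample(rep(c("train", "val", "test"),
               c(round(fr[["train"]] * n), round(fr[["val"]] * n),
                 n - round(fr[["train"]] * n) - round(fr[["val"]] * n))))
  })
  trainSet <- cropsToArrays(crops[split == "train"])
  # the scheduler tracks a fixed random validation subsample (crops arrive
  # grouped by eccentricity, so a head slice would be unrepresentative);
  # the full validation split is reserved for threshold tuning
  valCropIdx <- which(split == "val")
  valCropIdx <- withSeed(childSeed(config$seed, "valsub"),
                         sample(valCropIdx))
  valSet <- cropsToArrays(crops[valCropIdx[seq_len(min(96L,
                                                       length(valCropIdx)))]])

  netCfg <- if (config$network$tiny)
    tinyNetworkConfig(config$dataset$crop_size)
  else networkConfig(inputSize = config$dataset$crop_size)
  model <- buildNetwork(netCfg, seed = childSeed(config$seed, "init"))
  sched <- trainingSchedule(batchSize = config$network$batch_size,
                            maxEpochs = config$network$epochs)
  logLine("training %s network (%s parameters) for up to %d epochs",
          if (config$network$tiny) "tiny" else "full",
          format(countParams(model), big.mark = ","), sched@maxEpochs)
  trainNetwork(model, trainSet, valSet, sched,
               seed = childSeed(config$seed, "train"), augment = TRUE)
  hist <- model@state$history
  utils::write.csv(hist, file.path(config$output_dir, "history.csv"),
                   row.names = FALSE)
  logLine("final training loss %.2f, val loss %.2f",
          hist$loss[nrow(hist)], hist$val_loss[nrow(hist)])

  # a modest subset, spread across eccentricities by the same shuffle,
  # suffices to pick the operating point
  valCases <- lapply(crops[valCropIdx[seq_len(min(40L, length(valCropIdx)))]],
                     function(cr)
    list(image = cr$image, centres = cr$centres,
         coneWidthPx = cr$coneWidthPx))
  tuned <- tuneThresholds(model, valCases,
                          tGrid = config$detection$t_grid,
                          chiGrid = config$detection$chi_grid,
                          coneWidthPx = config$detection$fallback_width_px,
                          minDistanceFactor = config$detection$min_distance_factor)
  logLine("tuned T = %g, chi = %g (val Dice %.3f)", tuned$T, tuned$chi,
          tuned$dice)

  testCrops <- crops[split == "test"]
  detections <- list(); truths <- list(); widths <- numeric()
  for (i in seq_along(testCrops)) {
    cr <- testCrops[[i]]
    id <- sprintf("test%04d", i)
    pm <- predictMap(model, cr$image, id)
    detections[[id]] <- detectCones(
      pm, tuned$T, config$detection$min_distance_factor * cr$coneWidthPx)
    truths[[id]] <- cr$centres
    widths[id] <- cr$coneWidthPx
  }
  ev <- evaluateDataset(detections, truths, tuned$chi, widths,
                        c(config$dataset$crop_size, config$dataset$crop_size))
  utils::write.csv(ev$perImage,
                   file.path(config$output_dir, "metrics_per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$summary,
                   file.path(config$output_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  logLine("test mean Dice %.3f, TPR %.3f, FDR %.3f",
          ev$summary$mean[1L], ev$summary$mean[2L], ev$summary$mean[3L])
  list(tuned = tuned[c("T", "chi", "dice")], metrics = ev$perImage,
       summary = ev$summary, model = model, history = hist)
}
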