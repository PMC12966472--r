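#' Enumerate the synthetic acquisition condition grid
#'
#' Three image sets are simulated: noise only (every signal level crossed
#' with every frame count), residual aberration only (each selected eye at
#' each amplitude fraction), and the combined set (one eye each from a
#' larger pool, fixed signal/frames/fraction). With the study defaults this
#' gives 4 x 3 + 4 x 3 + 10 = 34 conditions.
#'
#' @param signalLevels pinhole signal grid, nW
#' @param frameCounts frames-averaged grid
#' @param aberrationEyes number of eyes in the aberration-only set
#' @param aberrationFractions amplitude-fraction grid
#' @param combinedEyes number of eyes in the combined set
#' @param combinedSignalNW,combinedFrames,combinedFraction combined-set
#'   acquisition settings
#' @return data.frame, one row per condition, with columns set, condition,
#'   signal_nW, n_frames, eye, fraction
#' @export
conditionGrid <- function(signalLevels = c(0.20, 0.25, 0.30, 0.35),
                          frameCounts = c(10L, 20L, 30L),
                          aberrationEyes = 4L,
                          aberrationFractions = c(0.1, 0.2, 0.3),
                          combinedEyes = 10L,
                          combinedSignalNW = 0.30, combinedFrames = 20L,
                          combinedFraction = 0.1) {
  noise <- expand.grid(signal_nW = signalLevels, n_frames = frameCounts)
  noise <- data.frame(set = "noise",
                      condition = sprintf("noise_s%.2f_f%d", noise$signal_nW,
                                          noise$n_frames),
                      signal_nW = noise$signal_nW, n_frames = noise$n_frames,
                      eye = NA_character_, fraction = NA_real_)
  ab <- expand.grid(eye = sprintf("eye%02d", seq_len(aberrationEyes)),
                    fraction = aberrationFractions,
                    stringsAsFactors = FALSE)
  ab <- data.frame(set = "aberration",
                   condition = sprintf("aberr_%s_a%.1f", ab$eye, ab$fraction),
                   signal_nW = NA_real_, n_frames = 1L,
                   eye = ab$eye, fraction = ab$fraction)
  comb <- data.frame(set = "combined",
                     condition = sprintf("comb_eye%02d", seq_len(combinedEyes)),
                     signal_nW = combinedSignalNW, n_frames = combinedFrames,
                     eye = sprintf("eye%02d", seq_len(combinedEyes)),
                     fraction = combinedFraction)
  rbind(noise, ab, comb)
}

#' Build the synthetic dataset manifest
#'
#' Enumerates every crop record of the synthetic grid: each condition at
#' each eccentricity with `imagesPerCondition` images split into
#' `cropsPerImage` crops, and assigns train/validation/test splits
#' stratified by (condition, eccentricity) so every stratum contributes to
#' every split in the requested proportions. With the study defaults
#' (34 conditions x 19 eccentricities x 100 images x 12 crops) the manifest
#' has 775,200 rows.
#'
#' @param conditions data.frame from [conditionGrid()]
#' @param eccentricities eccentricity grid in degrees (default 1 to 10 in
#'   0.5-degree steps: 19 levels)
#' @param imagesPerCondition images per (condition, eccentricity)
#' @param cropsPerImage crops per image
#' @param splitFractions named fractions for train/val/test
#' @param seed seed for the within-stratum image shuffle
#' @return data.frame manifest; one row per crop
#' @export
buildManifest <- function(conditions = conditionGrid(),
                          eccentricities = seq(1, 10, by = 0.5),
                          imagesPerCondition = 100L,
                          cropsPerImage = 12L,
                          splitFractions = c(train = 0.6, val = 0.2, test = 0.2),
                          seed = 1L) {
  if (abs(sum(splitFractions) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  if (imagesPerCondition < 1L || cropsPerImage < 1L || !nrow(conditions))
    stop("need at least one condition, image and crop", call. = FALSE)
  nTrain <- round(splitFractions[["train"]] * imagesPerCondition)
  nVal <- round(splitFractions[["val"]] * imagesPerCondition)
  nTest <- imagesPerCondition - nTrain - nVal
  if (nTest < 0) stop("split fractions inconsistent with image count", call. = FALSE)
  splitOfImage <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))

  strata <- merge(conditions, data.frame(eccentricity_deg = eccentricities))
  withSeed(seed, {
    blocks <- lapply(seq_len(nrow(strata)), function(i) {
      st <- strata[i, ]
      perm <- sample.int(imagesPerCondition)
      img <- seq_len(imagesPerCondition)
      data.frame(
        image_id = sprintf("%s_e%04.1f_i%03d", st$condition,
                           st$eccentricity_deg, img),
        source = "synthetic", set = st$set, condition = st$condition,
        signal_nW = st$signal_nW, n_frames = st$n_frames, eye = st$eye,
        fraction = st$fraction, eccentricity_deg = st$eccentricity_deg,
        participant_id = NA_character_, image_index = img,
        split = splitOfImage[order(perm)])
    })
    imgs <- do.call(rbind, blocks)
    n <- nrow(imgs)
    out <- imgs[rep(seq_len(n), each = cropsPerImage), ]
    out$crop_index <- rep(seq_len(cropsPerImage), times = n)
    rownames(out) <- NULL
    out
  })
}

#' Build a leakage-safe manifest for real annotated images
#'
#' All images from the same participant at the same eccentricity are kept
#' in a single split; split fractions are honoured at the group level
#' (approximately 60/20/20 by default).
#'
#' @param records data.frame with at least columns image_id, participant_id,
#'   eccentricity_deg
#' @param splitFractions named train/val/test fractions
#' @param seed seed for the group shuffle
#' @return `records` with a `split` column added and source = "real"
#' @export
buildRealManifest <- function(records,
                              splitFractions = c(train = 0.6, val = 0.2,
                                                 test = 0.2),
                              seed = 1L) {
  need <- c("image_id", "participant_id", "eccentricity_deg")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  grp <- interaction(records$participant_id, records$eccentricity_deg,
                     drop = TRUE)
  gl <- levels(grp)
  withSeed(seed, {
    perm <- sample(gl)
    nG <- length(gl)
    nTrain <- round(splitFractions[["train"]] * nG)
    nVal <- round(splitFractions[["val"]] * nG)
    splitOfGroup <- stats::setNames(
      rep(c("train", "val", "test"), c(nTrain, nVal, nG - nTrain - nVal)),
      perm)
    records$split <- unname(splitOfGroup[as.character(grp)])
    records$source <- "real"
    records
  })
}

#' Check manifest invariants
#'
#' Verifies that no real (participant, eccentricity) group spans two splits
#' and that crop records are unique.
#'
#' @param manifest a manifest data.frame
#' @return TRUE invisibly; otherwise an error
#' @export
validateManifest <- function(manifest) {
  real <- manifest[manifest$source == "real", , drop = FALSE]
  if (nrow(real)) {
    bad <- tapply(real$split,
                  interaction(real$participant_id, real$eccentricity_deg,
                              drop = TRUE),
                  function(s) length(unique(s)) > 1L)
    if (any(bad))
      stop("participant/eccentricity group spans multiple splits", call. = FALSE)
  }
  if ("crop_index" %in% names(manifest) &&
      anyDuplicated(manifest[, c("image_id", "crop_index")]))
    stop("duplicate crop records", call. = FALSE)
  invisible(TRUE)
}
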