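#' Class "ConeMosaic": ground-truth cone positions for one synthetic patch
#'
#' Holds the exact geometry and per-cone reflectance of a simulated cone
#' photoreceptor mosaic at a given retinal eccentricity. Centres are stored
#' in microns in a two-column matrix (x, y); with the default pixel scale of
#' 1 micron per pixel they coincide with 0-based pixel coordinates
#' (x = column, y = row).
#'
#' @slot eccentricity retinal eccentricity in degrees from the fovea
#' @slot centres n x 2 matrix of cone centres (x, y) in microns
#' @slot coneWidth mean cone diameter at this eccentricity, microns
#' @slot reflectivities per-cone relative reflectance, strictly positive
#' @slot fieldSize integer c(width, height) of the field in pixels
#' @slot pixelScale microns per pixel
#' @slot seed integer seed the mosaic was generated from
#' @exportClass ConeMosaic
setClass("ConeMosaic",
  representation(
    eccentricity   = "numeric",
    centres        = "matrix",
    coneWidth      = "numeric",
    reflectivities = "numeric",
    fieldSize      = "integer",
    pixelScale     = "numeric",
    seed           = "integer"
  )
)

setValidity("ConeMosaic", function(object) {
  msg <- character()
  n <- nrow(object@centres)
  if (ncol(object@centres) != 2L) msg <- c(msg, "centres must have two columns (x, y)")
  if (length(object@reflectivities) != n)
    msg <- c(msg, "one reflectivity per cone required")
  if (n > 0 && any(object@reflectivities <= 0))
    msg <- c(msg, "reflectivities must be strictly positive")
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 1L))
    msg <- c(msg, "fieldSize must be two positive integers")
  if (n > 0) {
    wUm <- object@fieldSize[1L] * object@pixelScale
    hUm <- object@fieldSize[2L] * object@pixelScale
    if (any(object@centres[, 1L] < 0 | object@centres[, 1L] > wUm |
            object@centres[, 2L] < 0 | object@centres[, 2L] > hUm))
      msg <- c(msg, "all centres must lie within the field bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Class "OpticsSpec": imaging-system parameters for PSF rendering
#'
#' @slot wavelengthNm imaging wavelength in nanometres (default 850)
#' @slot pupilDiameterMm pupil diameter in millimetres (default 5)
#' @slot pixelScaleUm retinal microns per image pixel
#' @slot pupilGridSize samples across the full pupil-plane array
#' @slot focalLengthMm reduced-eye focal length used to convert pupil-plane
#'   angles to retinal microns (default 17 mm, so 1 degree is about 291 um)
#' @exportClass OpticsSpec
setClass("OpticsSpec",
  representation(
    wavelengthNm    = "numeric",
    pupilDiameterMm = "numeric",
    pixelScaleUm    = "numeric",
    pupilGridSize   = "integer",
    focalLengthMm   = "numeric"
  )
)

setValidity("OpticsSpec", function(object) {
  ok <- object@wavelengthNm > 0 && object@pupilDiameterMm > 0 &&
    object@pixelScaleUm > 0 && object@focalLengthMm > 0 &&
    object@pupilGridSize >= 2L
  if (ok) TRUE else "wavelength, pupil diameter, pixel scale, focal length must all be > 0"
})

#' Class "Wavefront": Zernike description of residual ocular aberration
#'
#' Coefficients use the OSA/ANSI single-index convention, in microns.
#' `amplitudeFraction` scales the whole wavefront when a PSF is rendered, so
#' the RMS of the applied wavefront is `amplitudeFraction` times the RMS of
#' the stored coefficients.
#'
#' @slot coefficients Zernike mode coefficients in microns
#' @slot modeIndices OSA/ANSI single indices j matching `coefficients`
#' @slot amplitudeFraction unitless scale in (0, 1]
#' @slot eyeId label of the source eye
#' @exportClass Wavefront
setClass("Wavefront",
  representation(
    coefficients      = "numeric",
    modeIndices       = "integer",
    amplitudeFraction = "numeric",
    eyeId             = "character"
  )
)

setValidity("Wavefront", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@modeIndices))
    msg <- c(msg, "one OSA index per coefficient required")
  if (any(object@modeIndices < 0L)) msg <- c(msg, "OSA indices must be >= 0")
  if (anyDuplicated(object@modeIndices)) msg <- c(msg, "duplicate OSA indices")
  af <- object@amplitudeFraction
  if (length(af) != 1L || af <= 0 || af > 1)
    msg <- c(msg, "amplitudeFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Class "PSF": energy-normalised point spread function
#'
#' @slot kernel 2-D nonnegative matrix summing to 1
#' @slot pixelScaleUm microns per pixel of the kernel grid
#' @exportClass PSF
setClass("PSF",
  representation(kernel = "matrix", pixelScaleUm = "numeric")
)

setValidity("PSF", function(object) {
  msg <- character()
  if (any(object@kernel < 0)) msg <- c(msg, "kernel entries must be >= 0")
  if (abs(sum(object@kernel) - 1) > 1e-6) msg <- c(msg, "kernel must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Class "AcquisitionConfig": signal and noise model for frame simulation
#'
#' @slot signalNW time-average signal power at the pinhole, nanowatts
#' @slot noiseSigma standard deviation of the Gaussian white noise, detector units
#' @slot noiseMean mean of the additive noise, detector units
#' @slot nFrames number of single frames averaged into the final image
#' @slot unitsPerNW detector-unit calibration of the pinhole power
#' @slot seed integer noise seed
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(
    signalNW   = "numeric",
    noiseSigma = "numeric",
    noiseMean  = "numeric",
    nFrames    = "integer",
    unitsPerNW = "numeric",
    seed       = "integer"
  )
)

setValidity("AcquisitionConfig", function(object) {
  ok <- object@signalNW > 0 && object@nFrames >= 1L && object@noiseSigma >= 0 &&
    object@unitsPerNW > 0
  if (ok) TRUE else "need signalNW > 0, nFrames >= 1, noiseSigma >= 0, unitsPerNW > 0"
})

#' Class "LabelMap": Gaussian ground-truth training target
#'
#' Per-cone truncated Gaussians combined by maximum-intensity projection and
#' normalised to \[0, 255\].
#'
#' @slot values 2-D matrix in \[0, 255\]
#' @slot sigmaPx Gaussian standard deviation in pixels
#' @slot truncationRadiusPx truncation radius in pixels
#' @exportClass LabelMap
setClass("LabelMap",
  representation(values = "matrix", sigmaPx = "numeric",
                 truncationRadiusPx = "numeric")
)

setValidity("LabelMap", function(object) {
  if (any(object@values < 0) || any(object@values > 255))
    "label values must lie in [0, 255]" else TRUE
})

#' Class "ProbabilityMap": network-predicted cone probability image
#'
#' @slot values 2-D matrix in \[0, 255\]; intensity encodes cone likelihood
#' @slot sourceImageId identifier of the input image
#' @exportClass ProbabilityMap
setClass("ProbabilityMap",
  representation(values = "matrix", sourceImageId = "character")
)

setValidity("ProbabilityMap", function(object) {
  if (any(object@values < 0) || any(object@values > 255))
    "probability values must lie in [0, 255]" else TRUE
})

#' Class "DetectionResult": cone centres extracted from a probability map
#'
#' @slot centres n x 2 matrix of subpixel (x, y), 0-based pixel coordinates
#' @slot peakValues probability-map value at each detected peak
#' @slot threshold minimum intensity threshold T applied before peak finding
#' @slot minDistancePx minimum separation enforced between detections
#' @exportClass DetectionResult
setClass("DetectionResult",
  representation(centres = "matrix", peakValues = "numeric",
                 threshold = "numeric", minDistancePx = "numeric")
)

setValidity("DetectionResult", function(object) {
  n <- nrow(object@centres)
  if (n > 1) {
    d <- stats::dist(object@centres)
    # tiny slack for centroid refinement rounding
    if (min(d) < object@minDistancePx - 1e-9)
      return("detected centres closer than minDistancePx")
  }
  if (length(object@peakValues) != n) return("one peak value per centre required")
  TRUE
})

#' Class "MatchResult": one-to-one pairing of predicted and true cones
#'
#' @slot pairs data.frame with columns predicted, truth (1-based indices into
#'   the retained point sets) and distance (pixels)
#' @slot tp,fp,fn integer counts
#' @slot chi matching tolerance as a fraction of a cone width
#' @slot coneWidthPx cone width used, pixels
#' @slot excludedMarginPx edge-exclusion margin applied, pixels
#' @exportClass MatchResult
setClass("MatchResult",
  representation(pairs = "data.frame", tp = "integer", fp = "integer",
                 fn = "integer", chi = "numeric", coneWidthPx = "numeric",
                 excludedMarginPx = "numeric")
)

setValidity("MatchResult", function(object) {
  msg <- character()
  p <- object@pairs
  if (nrow(p)) {
    if (anyDuplicated(p$predicted)) msg <- c(msg, "a predicted cone is paired twice")
    if (anyDuplicated(p$truth)) msg <- c(msg, "a truth cone is paired twice")
    if (any(p$distance > object@chi * object@coneWidthPx + 1e-9))
      msg <- c(msg, "paired distance exceeds chi * cone width")
  }
  if (object@tp != nrow(p)) msg <- c(msg, "tp must equal the number of pairs")
  if (any(c(object@tp, object@fp, object@fn) < 0L)) msg <- c(msg, "negative counts")
  if (length(msg)) msg else TRUE
})

#' Class "ConeMetrics": Dice / true positive rate / false discovery rate
#'
#' @slot dice 2*TP / (2*TP + FP + FN)
#' @slot tpr TP / (TP + FN)
#' @slot fdr FP / (TP + FP)
#' @exportClass ConeMetrics
setClass("ConeMetrics",
  representation(dice = "numeric", tpr = "numeric", fdr = "numeric")
)

setValidity("ConeMetrics", function(object) {
  v <- c(object@dice, object@tpr, object@fdr)
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) "metrics must lie in [0, 1]" else TRUE
})

#' Class "NetworkConfig": architecture of the multi-scale encoder-decoder
#'
#' Each level runs parallel convolution branches; branch k stacks
#' `branchDepths[k]` 3x3 convolutions, giving effective receptive fields of
#' 3x3, 5x5, 7x7, ... The branches are concatenated, fused by a 1x1
#' convolution, and a 1x1-projected residual shortcut is added before the
#' final batch-norm + ReLU of the module.
#'
#' @slot inputSize input crop side in pixels (square), default 96
#' @slot depth number of encoder levels (pooling steps)
#' @slot baseFilters filters at the first level; doubles per level
#' @slot bottleneckFilters filters at the bottom of the U
#' @slot branchDepths integer vector of stacked-3x3 counts per parallel branch
#' @slot useResidual include the residual shortcut projections
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(inputSize = "integer", depth = "integer",
                 baseFilters = "integer", bottleneckFilters = "integer",
                 branchDepths = "integer", useResidual = "logical")
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (object@inputSize %% (2L^object@depth) != 0L)
    msg <- c(msg, "input size must be divisible by 2^depth")
  if (object@depth < 1L || object@baseFilters < 1L || length(object@branchDepths) < 1L)
    msg <- c(msg, "depth, baseFilters, branchDepths must be positive")
  if (length(msg)) msg else TRUE
})

#' Class "TrainingSchedule": optimisation schedule for heatmap regression
#'
#' Mean-squared-error loss on \[0, 255\] label maps, Adam optimiser, plateau
#' learning-rate halving and early stopping driven by validation loss.
#'
#' @slot initialLR initial learning rate (1e-3; 1e-4 for transfer learning)
#' @slot lrDecayFactor multiplicative decay on plateau (0.5)
#' @slot lrPatience epochs without sufficient improvement before decay (5)
#' @slot lrFloor minimum learning rate (1e-5)
#' @slot improvementThreshold required validation-loss drop, in MSE units on
#'   \[0, 255\] labels (1.0)
#' @slot earlyStopPatience epochs without improvement before stopping (7)
#' @slot batchSize minibatch size (32)
#' @slot maxEpochs hard cap on epochs for a run
#' @slot folds cross-validation folds the training groups are split into (4)
#' @exportClass TrainingSchedule
setClass("TrainingSchedule",
  representation(initialLR = "numeric", lrDecayFactor = "numeric",
                 lrPatience = "integer", lrFloor = "numeric",
                 improvementThreshold = "numeric", earlyStopPatience = "integer",
                 batchSize = "integer", maxEpochs = "integer", folds = "integer")
)

setValidity("TrainingSchedule", function(object) {
  ok <- object@initialLR > 0 && object@lrFloor > 0 &&
    object@lrDecayFactor > 0 && object@lrDecayFactor < 1 &&
    object@lrPatience >= 1L && object@earlyStopPatience >= 1L &&
    object@batchSize >= 1L && object@maxEpochs >= 1L && object@folds >= 1L
  if (ok) TRUE else "invalid schedule parameters"
})

#' Class "ConeUNet": the multi-scale encoder-decoder model
#'
#' Parameters live in an environment so training updates in place.
#'
#' @slot config a [NetworkConfig-class]
#' @slot state environment holding the layer list and parameters
#' @exportClass ConeUNet
setClass("ConeUNet",
  representation(config = "NetworkConfig", state = "environment")
)
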