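#' Accessors for coneUNet classes
#'
#' Small accessor family: `coneCentres` returns the (x, y) coordinate matrix
#' of a [ConeMosaic-class] (microns) or [DetectionResult-class] (pixels);
#' `reflectivities` the per-cone reflectances; `coneWidth` the mean cone
#' diameter; `kernelMatrix` a PSF's kernel; `mapValues` the pixel matrix of a
#' label or probability map.
#'
#' @param x the object
#' @return the slot contents, see details
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("coneCentres", function(x) standardGeneric("coneCentres"))

#' @rdname accessors
#' @export
setGeneric("reflectivities", function(x) standardGeneric("reflectivities"))

#' @rdname accessors
#' @export
setGeneric("coneWidth", function(x) standardGeneric("coneWidth"))

#' @rdname accessors
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setMethod("coneCentres", "ConeMosaic", function(x) x@centres)

#' @rdname accessors
#' @export
setMethod("coneCentres", "DetectionResult", function(x) x@centres)

#' @rdname accessors
#' @export
setMethod("reflectivities", "ConeMosaic", function(x) x@reflectivities)

#' @rdname accessors
#' @export
setMethod("coneWidth", "ConeMosaic", function(x) x@coneWidth)

#' @rdname accessors
#' @export
setMethod("kernelMatrix", "PSF", function(x) x@kernel)

#' @rdname accessors
#' @export
setMethod("mapValues", "LabelMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "ProbabilityMap", function(x) x@values)

setMethod("show", "ConeMosaic", function(object) {
  cat(sprintf(
    "ConeMosaic: %d cones at %.1f deg, field %d x %d px (%.2f um/px), cone width %.2f um\n",
    nrow(object@centres), object@eccentricity, object@fieldSize[1L],
    object@fieldSize[2L], object@pixelScale, object@coneWidth))
})

setMethod("show", "PSF", function(object) {
  cat(sprintf("PSF: %d x %d kernel at %.3f um/px, peak %.3g\n",
              nrow(object@kernel), ncol(object@kernel), object@pixelScaleUm,
              max(object@kernel)))
})

setMethod("show", "Wavefront", function(object) {
  cat(sprintf("Wavefront '%s': %d Zernike modes, RMS %.4f um, amplitude fraction %.2f\n",
              object@eyeId, length(object@coefficients),
              wavefrontRMS(object, scaled = FALSE), object@amplitudeFraction))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d, FP %d, FN %d (chi = %.2f, cone width %.2f px)\n",
              object@tp, object@fp, object@fn, object@chi, object@coneWidthPx))
})

setMethod("show", "ConeMetrics", function(object) {
  cat(sprintf("Dice %.4f | TPR %.4f | FDR %.4f\n",
              object@dice, object@tpr, object@fdr))
})

setMethod("show", "ConeUNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ConeUNet: input %dx%d, depth %d, base %d filters, bottleneck %d, branches {%s}, %s parameters\n",
    cfg@inputSize, cfg@inputSize, cfg@depth, cfg@baseFilters,
    cfg@bottleneckFilters,
    paste(2L * cfg@branchDepths + 1L, collapse = ","),
    format(countParams(object), big.mark = ",")))
})
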