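#' Construct an AcquisitionConfig
#'
#' Defaults put the 0.30 nW / 20-frame condition near 15 dB SNR with the
#' default calibration of 1000 detector units per nanowatt: the scene mean
#' is then 300 units and the averaged-image noise sd is
#' `240 / sqrt(20) = 53.7` units.
#'
#' @param signalNW time-average signal power at the pinhole, nanowatts
#'   (study grid: 0.20 to 0.35 in steps of 0.05)
#' @param noiseSigma Gaussian noise sd, detector units
#' @param noiseMean Gaussian noise mean, detector units
#' @param nFrames frames averaged (study grid: 10, 20 or 30)
#' @param unitsPerNW detector units per nanowatt
#' @param seed integer noise seed
#' @return an [AcquisitionConfig-class]
#' @export
acquisitionConfig <- function(signalNW = 0.30, noiseSigma = 240,
                              noiseMean = 0, nFrames = 20L,
                              unitsPerNW = 1000, seed = 1L) {
  new("AcquisitionConfig", signalNW = signalNW, noiseSigma = noiseSigma,
      noiseMean = noiseMean, nFrames = as.integer(nFrames),
      unitsPerNW = unitsPerNW, seed = as.integer(seed))
}

#' Scale a scene to a target pinhole signal power
#'
#' Rescales the scene so its mean equals `signalNW * unitsPerNW` detector
#' units; linear in `signalNW`.
#'
#' @param scene numeric matrix with positive mean
#' @param signalNW target signal in nanowatts
#' @param unitsPerNW calibration, detector units per nanowatt
#' @return the rescaled scene
#' @export
setSignal <- function(scene, signalNW, unitsPerNW = 1000) {
  stopIfNot2D(scene, "scene")
  if (signalNW <= 0) stop("signalNW must be > 0", call. = FALSE)
  m <- mean(scene)
  if (m <= 0) stop("scene mean must be positive", call. = FALSE)
  scene * (signalNW * unitsPerNW / m)
}

#' Simulate one noisy frame
#'
#' Adds i.i.d. Gaussian white noise to a signal-scaled scene. Reproducible
#' from `(config seed, frame index)`; negative detector values are clipped
#' at zero.
#'
#' @param scene signal-scaled scene (detector units)
#' @param config an [AcquisitionConfig-class]
#' @param frameIndex 1-based frame number
#' @return one noisy frame, same dimensions
#' @export
simulateFrame <- function(scene, config, frameIndex = 1L) {
  stopIfNot2D(scene, "scene")
  frame <- withSeed(childSeed(config@seed, "frame", frameIndex), {
    scene + config@noiseMean +
      matrix(stats::rnorm(length(scene), 0, config@noiseSigma),
             nrow(scene), ncol(scene))
  })
  frame[frame < 0] <- 0
  frame
}

#' Average single frames into the final image
#'
#' Pixel-wise arithmetic mean; no registration is needed because the
#' simulation has no eye motion.
#'
#' @param frames list of equally sized numeric matrices
#' @return the averaged image
#' @export
averageFrames <- function(frames) {
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("frames differ in shape", call. = FALSE)
  Reduce(`+`, frames) / length(frames)
}

#' Simulate a frame-averaged acquisition of a scene
#'
#' Convenience wrapper: scales the scene to the configured signal, simulates
#' `nFrames` noisy frames and averages them.
#'
#' @param scene pre-acquisition (blurred) scene
#' @param config an [AcquisitionConfig-class]
#' @return the averaged image in detector units
#' @export
acquireImage <- function(scene, config) {
  scaled <- setSignal(scene, config@signalNW, config@unitsPerNW)
  averageFrames(lapply(seq_len(config@nFrames), function(i)
    simulateFrame(scaled, config, i)))
}

#' Signal-to-noise ratio of an averaged image
#'
#' `SNR = 20 log10(mean signal / effective noise sd)` where the effective
#' noise sd of an N-frame average is `noiseSigma / sqrt(N)`. This mean/sd
#' definition is the package's own documented convention.
#'
#' @param image averaged image in detector units
#' @param config the [AcquisitionConfig-class] used to acquire it
#' @return SNR in decibels (`Inf` for zero noise)
#' @export
snr <- function(image, config) {
  if (config@noiseSigma == 0) return(Inf)
  20 * log10(mean(image) / (config@noiseSigma / sqrt(config@nFrames)))
}

#' Export an averaged image as 8-bit grayscale
#'
#' Images are kept continuous internally and quantised to 8 bits only on
#' export. Range defaults to \[0, max(image)\].
#'
#' @param image numeric matrix
#' @param path output path ending in .png or .tif/.tiff
#' @param lo,hi intensity range mapped to 0..255
#' @return the path, invisibly
#' @export
writeImage8bit <- function(image, path, lo = 0, hi = max(image)) {
  x <- clip01((image - lo) / (hi - lo), 0, 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(round(x * 255) / 255, path)
  } else {
    tiff::writeTIFF(round(x * 255) / 255, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write a float scene as 32-bit TIFF
#' @param image numeric matrix (any nonnegative range)
#' @param path output .tif path
#' @return the path, invisibly
#' @export
writeSceneTIFF <- function(image, path) {
  tiff::writeTIFF(image / max(max(image), 1e-12), path,
                  bits.per.sample = 32L)
  invisible(path)
}
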