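#' Construct an OpticsSpec
#'
#' @param wavelengthNm imaging wavelength, nanometres
#' @param pupilDiameterMm pupil diameter, millimetres
#' @param pixelScaleUm retinal microns per pixel of the rendered PSF
#' @param pupilGridSize samples across the full pupil-plane array
#' @param focalLengthMm reduced-eye focal length for angle-to-retina
#'   conversion
#' @return an [OpticsSpec-class]
#' @export
opticsSpec <- function(wavelengthNm = 850, pupilDiameterMm = 5,
                       pixelScaleUm = 1.0, pupilGridSize = 512L,
                       focalLengthMm = 17) {
  new("OpticsSpec", wavelengthNm = wavelengthNm,
      pupilDiameterMm = pupilDiameterMm, pixelScaleUm = pixelScaleUm,
      pupilGridSize = as.integer(pupilGridSize), focalLengthMm = focalLengthMm)
}

#' Construct a Wavefront from OSA-indexed Zernike coefficients
#'
#' @param coefficients coefficients in microns
#' @param modeIndices OSA/ANSI single indices (default `seq_along - 1`)
#' @param amplitudeFraction fraction of the amplitude applied when rendering
#' @param eyeId label
#' @return a [Wavefront-class]
#' @export
wavefront <- function(coefficients, modeIndices = seq_along(coefficients) - 1L,
                      amplitudeFraction = 1.0, eyeId = "eye") {
  new("Wavefront", coefficients = as.numeric(coefficients),
      modeIndices = as.integer(modeIndices),
      amplitudeFraction = amplitudeFraction, eyeId = eyeId)
}

# OSA/ANSI single index -> (n, m)
osaToNM <- function(j) {
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  cbind(n = n, m = m)
}

# Normalised Zernike polynomial Z_j on (rho, theta); unit RMS over the disk.
zernikeEval <- function(j, rho, theta) {
  nm <- osaToNM(j)
  n <- nm[1L, "n"]; m <- nm[1L, "m"]
  am <- abs(m)
  R <- 0
  for (k in 0:((n - am) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k)) *
      rho^(n - 2 * k)
  }
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  if (m > 0) norm * R * cos(am * theta)
  else if (m < 0) norm * R * sin(am * theta)
  else norm * R
}

#' Total RMS wavefront error of a Wavefront
#'
#' With unit-RMS normalised Zernike modes the RMS over the pupil is the
#' Euclidean norm of the coefficients. Piston, tip and tilt (OSA 0-2) are
#' excluded: they displace the image but do not blur it.
#'
#' @param wf a [Wavefront-class]
#' @param scaled if TRUE, apply the wavefront's amplitude fraction
#' @return RMS wavefront error in microns
#' @export
wavefrontRMS <- function(wf, scaled = TRUE) {
  keep <- wf@modeIndices >= 3L
  r <- sqrt(sum(wf@coefficients[keep]^2))
  if (scaled) r * wf@amplitudeFraction else r
}

#' Set the amplitude fraction of a wavefront
#'
#' A fixed proportion of the measured aberration amplitude models the
#' residual error remaining after adaptive-optics correction; the RMS of the
#' applied wavefront scales linearly with the fraction.
#'
#' @param wf a [Wavefront-class]
#' @param fraction value in (0, 1]
#' @return the rescaled [Wavefront-class]
#' @export
setAmplitudeFraction <- function(wf, fraction) {
  wf@amplitudeFraction <- fraction
  validObject(wf)
  wf
}

#' Average Zernike time series into a single Wavefront per eye
#'
#' Takes the arithmetic mean of each mode's coefficient sequence; the result
#' carries amplitude fraction 1.
#'
#' @param series data.frame with columns `mode_index`, `coefficient_um` and
#'   optionally `time_s` (one eye), or a named list of per-mode numeric
#'   vectors whose names are OSA indices
#' @param eyeId label for the resulting wavefront
#' @return a [Wavefront-class]
#' @export
meanZernikeOverTime <- function(series, eyeId = "eye") {
  if (is.data.frame(series)) {
    if (!nrow(series)) stop("empty Zernike series", call. = FALSE)
    agg <- tapply(series$coefficient_um, series$mode_index, mean)
    modes <- as.integer(names(agg))
    coefs <- as.numeric(agg)
  } else {
    if (!length(series) || any(!lengths(series)))
      stop("empty Zernike series", call. = FALSE)
    modes <- as.integer(names(series))
    coefs <- vapply(series, mean, numeric(1))
  }
  o <- order(modes)
  wavefront(coefs[o], modes[o], amplitudeFraction = 1.0, eyeId = eyeId)
}

#' Select the eyes with the lowest total RMS wavefront error
#'
#' @param eyes list of [Wavefront-class] objects (mean coefficients per eye)
#' @param n how many to keep
#' @return list of n wavefronts, ascending RMS
#' @export
selectLowestRmsEyes <- function(eyes, n) {
  if (n > length(eyes)) stop("n exceeds the number of eyes", call. = FALSE)
  rms <- vapply(eyes, wavefrontRMS, numeric(1), scaled = FALSE)
  eyes[order(rms)][seq_len(n)]
}

fftShift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

#' Render the point spread function of a (scaled) wavefront
#'
#' Fourier-optics PSF of a circular pupil: the pupil field carries phase
#' `(2 pi / lambda) * amplitudeFraction * W(rho, theta)` built from the
#' wavefront's Zernike modes (piston/tip/tilt excluded), and the PSF is the
#' squared modulus of its Fourier transform, sampled so one PSF pixel spans
#' `pixelScaleUm` on the retina via the spec's focal conversion. With an
#' all-zero wavefront the result is the Airy pattern. The kernel is cropped
#' to the smallest centred odd window holding `1 - cropTol` of the energy
#' and renormalised to unit sum.
#'
#' @param wf a [Wavefront-class]
#' @param optics an [OpticsSpec-class]
#' @param cropTol energy fraction allowed outside the cropped kernel
#' @param maxKernel largest kernel side returned, pixels (odd)
#' @return a [PSF-class]
#' @examples
#' psf <- psfFromWavefront(wavefront(numeric(15)), opticsSpec())
#' sum(kernelMatrix(psf))
#' @export
psfFromWavefront <- function(wf, optics, cropTol = 1e-4, maxKernel = 63L) {
  lamUm <- optics@wavelengthNm / 1000
  fUm <- optics@focalLengthMm * 1000
  dUm <- optics@pupilDiameterMm * 1000
  angPix <- optics@pixelScaleUm / fUm            # rad per PSF pixel
  # Nyquist for the diffraction cutoff D/lambda cycles/rad
  if (angPix > lamUm / (2 * dUm))
    warning("pixel scale undersamples the Airy core; PSF will be aliased")
  N <- optics@pupilGridSize
  L <- lamUm / angPix                             # pupil-plane array width, um
  pupilSamples <- dUm / (L / N)
  if (pupilSamples < 64)
    stop(sprintf("pupil sampled by %.0f < 64 points across its diameter; increase pupilGridSize",
                 pupilSamples), call. = FALSE)
  ax <- (seq_len(N) - 1 - floor(N / 2)) * (L / N) # um in the pupil plane
  X <- matrix(ax, N, N); Y <- t(X)
  rho <- sqrt(X^2 + Y^2) / (dUm / 2)
  inside <- rho <= 1
  phase <- matrix(0, N, N)
  use <- wf@modeIndices >= 3L & wf@coefficients != 0
  if (any(use)) {
    theta <- atan2(Y, X)
    wmap <- matrix(0, N, N)
    ri <- rho[inside]; ti <- theta[inside]
    for (i in which(use)) {
      wmap[inside] <- wmap[inside] +
        wf@amplitudeFraction * wf@coefficients[i] *
        zernikeEval(wf@modeIndices[i], ri, ti)
    }
    phase <- (2 * pi / lamUm) * wmap
  }
  field <- matrix(0 + 0i, N, N)
  field[inside] <- exp(1i * phase[inside])
  psf <- Mod(fftShift2(stats::fft(field)))^2
  psf <- psf / sum(psf)
  # smallest centred odd crop keeping >= 1 - cropTol of the energy
  c0 <- floor(N / 2) + 1L
  half <- 1L
  repeat {
    win <- psf[(c0 - half):(c0 + half), (c0 - half):(c0 + half)]
    if (sum(win) >= 1 - cropTol || (2L * half + 1L) >= min(N, maxKernel)) break
    half <- half + 1L
  }
  k <- psf[(c0 - half):(c0 + half), (c0 - half):(c0 + half)]
  new("PSF", kernel = k / sum(k), pixelScaleUm = optics@pixelScaleUm)
}

#' Strehl ratio of a wavefront's PSF
#'
#' Peak of the aberrated PSF divided by the diffraction-limited peak under
#' the same optics; 1 for a perfect system.
#'
#' @param wf a [Wavefront-class]
#' @param optics an [OpticsSpec-class]
#' @return the Strehl ratio
#' @export
strehlRatio <- function(wf, optics) {
  ab <- psfFromWavefront(wf, optics)
  dl <- psfFromWavefront(wavefront(numeric(1), 0L, eyeId = wf@eyeId), optics)
  max(ab@kernel) / max(dl@kernel)
}

# Linear "same" convolution with reflect padding, via FFT.
fftConvolveSame <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  if (kh %% 2L == 0L || kw %% 2L == 0L)
    stop("kernel dimensions must be odd", call. = FALSE)
  h2 <- (kh - 1L) %/% 2L; w2 <- (kw - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  if (h2 >= H || w2 >= W) stop("kernel larger than image", call. = FALSE)
  # reflect padding (edge pixel not duplicated)
  ri <- c(rev(seq_len(h2) + 1L), seq_len(H), H - seq_len(h2))
  ci <- c(rev(seq_len(w2) + 1L), seq_len(W), W - seq_len(w2))
  xp <- x[ri, ci, drop = FALSE]
  Hp <- nrow(xp); Wp <- ncol(xp)
  P1 <- Hp + kh - 1L; P2 <- Wp + kw - 1L
  A <- matrix(0, P1, P2); A[1:Hp, 1:Wp] <- xp
  B <- matrix(0, P1, P2); B[1:kh, 1:kw] <- k
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P1 * P2)
  # "same" region of the padded image, then strip the reflect margins
  conv[(h2 + 1L):(h2 + Hp), (w2 + 1L):(w2 + Wp)][h2 + seq_len(H), w2 + seq_len(W)]
}

#' Blur a scene with a point spread function
#'
#' 2-D convolution with reflect padding (avoids dark frame edges in training
#' crops); output has the scene's dimensions and conserves total intensity
#' up to boundary effects.
#'
#' @param scene numeric matrix, the pre-optics scene
#' @param psf a [PSF-class]
#' @param pixelScale microns per pixel of the scene
#' @return blurred scene, same dimensions
#' @export
applyOptics <- function(scene, psf, pixelScale = 1.0) {
  stopIfNot2D(scene, "scene")
  if (abs(psf@pixelScaleUm - pixelScale) > 1e-9)
    stop("scene and PSF pixel scales differ", call. = FALSE)
  fftConvolveSame(scene, psf@kernel)
}

#' Synthetic Zernike time-series fixture
#'
#' Stand-in for measured per-eye aberration time series when real CSVs are
#' unavailable: per-mode coefficients fluctuate around an eye-specific mean
#' whose magnitude falls off with radial order (amplitude proportional to
#' `1 / n^2`), a crude match to the decreasing power of higher-order ocular
#' aberrations. Clearly synthetic; real data in the same long format can be
#' supplied instead.
#'
#' @param nEyes number of eyes
#' @param nTime time samples per mode
#' @param maxOrder highest radial order n included (OSA modes 3..j(maxOrder))
#' @param rmsScaleUm typical per-eye total RMS, microns
#' @param seed integer seed
#' @return data.frame with columns eye_id, mode_index, time_s, coefficient_um
#' @export
syntheticZernikeSeries <- function(nEyes = 10L, nTime = 50L, maxOrder = 4L,
                                   rmsScaleUm = 0.08, seed = 1L) {
  jMax <- (maxOrder * (maxOrder + 3L)) %/% 2L    # last OSA index of order maxOrder
  modes <- 3:jMax
  nOrd <- osaToNM(modes)[, "n"]
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(nEyes), function(e) {
      amp <- rmsScaleUm * (2 / nOrd^2)
      mu <- stats::rnorm(length(modes), 0, amp)
      do.call(rbind, lapply(seq_along(modes), function(i) {
        data.frame(eye_id = sprintf("eye%02d", e), mode_index = modes[i],
                   time_s = seq(0, by = 0.1, length.out = nTime),
                   coefficient_um = mu[i] + stats::rnorm(nTime, 0, 0.15 * amp[i]))
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Read a Zernike coefficient table
#'
#' Long CSV with columns `eye_id`, `mode_index`, `coefficient_um` and
#' optionally `time_s`.
#'
#' @param path CSV path
#' @return data.frame
#' @export
readZernikeCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("eye_id", "mode_index", "coefficient_um")
  if (!all(need %in% names(df)))
    stop("Zernike CSV needs columns eye_id, mode_index, coefficient_um",
         call. = FALSE)
  df
}

#' Collapse a multi-eye Zernike series into per-eye mean wavefronts
#'
#' @param series data.frame as returned by [readZernikeCSV()] or
#'   [syntheticZernikeSeries()]
#' @return named list of [Wavefront-class], one per eye
#' @export
wavefrontsFromSeries <- function(series) {
  ids <- unique(series$eye_id)
  out <- lapply(ids, function(id)
    meanZernikeOverTime(series[series$eye_id == id, , drop = FALSE], eyeId = id))
  names(out) <- ids
  out
}
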