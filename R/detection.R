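#' Extract cone centres from a probability map
#'
#' Pixels below the minimum intensity threshold `T` are zeroed, local
#' maxima separated by at least `minDistancePx` are identified (greedy
#' suppression in descending intensity; exact ties resolved by scan order),
#' and each surviving peak is refined to the probability-weighted centroid
#' of the above-threshold pixels within its neighbourhood, using the raw
#' map values as weights. If centroid refinement pulls two centres closer
#' than the minimum distance, the peak with the larger above-threshold mass
#' is kept.
#'
#' @param map a [ProbabilityMap-class] or numeric matrix in \[0, 255\]
#' @param threshold minimum intensity T in \[0, 255\]
#' @param minDistancePx minimum separation between detections, pixels
#' @return a [DetectionResult-class]; centres are 0-based (x = column,
#'   y = row) subpixel coordinates
#' @examples
#' m <- makeLabelMap(cbind(c(20, 40), c(30, 30)), 8, c(64L, 64L))
#' detectCones(mapValues(m), threshold = 120, minDistancePx = 4)
#' @export
detectCones <- function(map, threshold, minDistancePx) {
  vals <- if (is(map, "ProbabilityMap")) map@values else map
  stopIfNot2D(vals, "probability map")
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  H <- nrow(vals); W <- ncol(vals)
  v <- vals
  v[v < threshold] <- 0

  empty <- function() new("DetectionResult",
                          centres = matrix(0, 0L, 2L), peakValues = numeric(),
                          threshold = threshold, minDistancePx = minDistancePx)
  if (all(v == 0)) return(empty())

  # local maxima: pixel equals the maximum of its window (box of the
  # minimum-distance radius) and clears the threshold
  r <- max(1L, floor(minDistancePx))
  size <- 2L * r + 1L
  dil <- EBImage::dilate(v / 255, EBImage::makeBrush(size, "box")) * 255
  cand <- which(v >= dil - 1e-9 & v > 0, arr.ind = TRUE)
  if (!nrow(cand)) return(empty())
  pv <- v[cand]
  o <- order(-pv, cand[, 1L], cand[, 2L])
  cand <- cand[o, , drop = FALSE]
  pv <- pv[o]

  # greedy minimum-distance suppression on the pixel peaks
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dy <- cand[keep, 1L] - cand[i, 1L]
    dx <- cand[keep, 2L] - cand[i, 2L]
    if (all(dx * dx + dy * dy >= minDistancePx^2)) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  pv <- pv[keep]

  # probability-weighted centroid over the above-threshold neighbourhood,
  # weighted by the raw (unthresholded) map values
  cen <- matrix(0, nrow(cand), 2L)
  mass <- numeric(nrow(cand))
  rc <- max(1L, ceiling(minDistancePx))
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1L]; x <- cand[i, 2L]
    ys <- max(1L, y - rc):min(H, y + rc)
    xs <- max(1L, x - rc):min(W, x + rc)
    blk <- vals[ys, xs, drop = FALSE]
    sup <- v[ys, xs, drop = FALSE] > 0
    wts <- blk * sup
    s <- sum(wts)
    mass[i] <- s
    # 0-based coordinates
    cen[i, 1L] <- sum(wts * matrix(xs - 1L, length(ys), length(xs),
                                   byrow = TRUE)) / s
    cen[i, 2L] <- sum(wts * matrix(ys - 1L, length(ys), length(xs))) / s
  }

  # refinement may merge neighbours: keep the larger-mass peak
  o <- order(-mass)
  keep <- logical(length(o))
  for (i in o) {
    sel <- which(keep)
    if (!length(sel)) { keep[i] <- TRUE; next }
    d2 <- (cen[sel, 1L] - cen[i, 1L])^2 + (cen[sel, 2L] - cen[i, 2L])^2
    if (all(d2 >= minDistancePx^2)) keep[i] <- TRUE
  }
  ord <- which(keep)[order(-pv[keep])]
  new("DetectionResult", centres = cen[ord, , drop = FALSE],
      peakValues = pv[ord], threshold = threshold,
      minDistancePx = minDistancePx)
}

#' Estimate cone width from an image's power spectrum
#'
#' The quasi-regular cone mosaic produces an annular peak (Yellott's ring)
#' in the image power spectrum whose radius encodes the modal row frequency
#' of the hexagonal packing. The image is Hann-windowed and mean-subtracted,
#' the 2-D power spectrum is radially averaged at the FFT's natural
#' resolution, and the smooth spectral envelope (reflectivity variation,
#' blur and noise roll-off) is removed by a log-log smoothing-spline fit.
#' The ring appears as a narrow positive excess over the envelope: the
#' lowest-frequency prominent excess peak inside the plausible spacing band
#' is taken as the modal row frequency, converted to centre-to-centre
#' spacing via the hexagonal row-spacing factor `2 / sqrt(3)` and to width
#' by the configured width/spacing ratio. If no convincing ring is found
#' the fallback width is returned with a warning.
#'
#' Reliable estimates need a field holding a few hundred cones (roughly
#' 200 x 200 px and upward at 1 um/px); on small noisy crops the ring is
#' statistically weak and the fallback is common.
#'
#' @param image numeric matrix containing a cone mosaic
#' @param pixelScaleUm microns per pixel (unit bookkeeping only; the return
#'   value is in pixels)
#' @param widthToSpacing cone width as a fraction of spacing
#' @param spacingRangePx plausible spacing range searched, pixels
#' @param fallbackWidthPx width returned when no spectral peak is found
#' @param minLogExcess required log-power excess of the ring over the
#'   fitted envelope
#' @param envelopeDf degrees of freedom of the log-log envelope spline
#' @return estimated cone width in pixels
#' @examples
#' sc <- renderScene(generateMosaic(5, c(300L, 300L), seed = 1))
#' estimateConeWidth(sc)  # ~5.6 px
#' @export
estimateConeWidth <- function(image, pixelScaleUm = 1.0,
                              widthToSpacing = 0.8,
                              spacingRangePx = c(3, 20),
                              fallbackWidthPx = 6,
                              minLogExcess = log(1.6),
                              envelopeDf = 6) {
  stopIfNot2D(image)
  H <- nrow(image); W <- ncol(image)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  x <- (image - mean(image)) * outer(hann(H), hann(W))
  P <- Mod(stats::fft(x))^2
  # radial frequency of each FFT bin, cycles per pixel
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  nb <- max(48L, min(H, W) %/% 2L)
  bin <- pmin(nb, 1L + floor(fr / 0.5 * nb))
  prof <- as.numeric(tapply(as.vector(P), as.vector(bin), mean))
  freq <- (sort(unique(as.vector(bin))) - 0.5) * 0.5 / nb
  keep <- freq > 0.01 & prof > 0
  if (sum(keep) < 10L) {
    warning("image too small for a spectral estimate; using fallback cone width")
    return(fallbackWidthPx)
  }
  lp <- log(prof[keep])
  lf <- log(freq[keep])
  fit <- stats::smooth.spline(lf, lp, df = envelopeDf)
  excess <- lp - stats::predict(fit, lf)$y
  f2 <- freq[keep]
  hex <- 2 / sqrt(3)   # row frequency of hexagonal packing at unit spacing
  inBand <- f2 >= hex / spacingRangePx[2L] & f2 <= hex / spacingRangePx[1L]
  if (!any(inBand)) {
    warning("spacing search band empty; using fallback cone width")
    return(fallbackWidthPx)
  }
  n <- length(excess)
  isMax <- c(FALSE, excess[2:(n - 1)] > excess[1:(n - 2)] &
                    excess[2:(n - 1)] >= excess[3:n], FALSE)
  cand <- which(isMax & inBand & excess >= minLogExcess)
  if (!length(cand)) {
    warning("no spectral ring found; using fallback cone width")
    return(fallbackWidthPx)
  }
  # harmonics of the packing sit above the fundamental: take the
  # lowest-frequency peak among those comparable to the strongest
  pk <- cand[excess[cand] >= 0.5 * max(excess[cand])][1L]
  widthToSpacing * hex / f2[pk]
}
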