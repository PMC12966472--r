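#' Centre-to-centre cone spacing at a retinal eccentricity
#'
#' Parametric model of mean cone spacing as a function of eccentricity,
#' linear in degrees: `s(e) = s0 + k * e`. The defaults (`s0 = 4` um,
#' `k = 0.6` um/deg) approximate published histology trends over 1-10
#' degrees: spacing grows monotonically from about 4.6 um at 1 degree to
#' 10 um at 10 degrees.
#'
#' @param eccentricityDeg retinal eccentricity in degrees, in (0, 10]
#' @param s0 spacing intercept, microns
#' @param k spacing slope, microns per degree
#' @return centre-to-centre spacing in microns
#' @examples
#' coneSpacing(5)  # 7 um with the default model
#' @export
coneSpacing <- function(eccentricityDeg, s0 = 4.0, k = 0.6) {
  if (any(eccentricityDeg <= 0) || any(eccentricityDeg > 10))
    stop("eccentricity must lie in (0, 10] degrees", call. = FALSE)
  s0 + k * eccentricityDeg
}

#' Generate a ground-truth cone mosaic
#'
#' Places cone centres on a hexagonal lattice at the eccentricity-dependent
#' spacing, adds isotropic Gaussian positional jitter (sd = 0.05 spacing),
#' and rejects cones that fall outside the field or closer than half a
#' spacing to an already-accepted neighbour, so no two cones merge. Each
#' cone receives an independent log-normal relative reflectivity
#' (median 1, sdlog 0.35), mimicking the reflectance variability seen
#' between retinae.
#'
#' @param eccentricityDeg retinal eccentricity in degrees
#' @param fieldSize integer c(width, height) in pixels (default 480 x 300)
#' @param seed integer seed; identical seeds give identical mosaics
#' @param pixelScale microns per pixel (default 1)
#' @param jitterFrac jitter sd as a fraction of spacing
#' @param sdlog log-sd of the reflectivity distribution
#' @param s0,k spacing model parameters, see [coneSpacing()]
#' @return a [ConeMosaic-class]
#' @examples
#' m <- generateMosaic(1, c(480L, 300L), seed = 1)
#' nrow(coneCentres(m))
#' @export
generateMosaic <- function(eccentricityDeg, fieldSize = c(480L, 300L),
                           seed = 1L, pixelScale = 1.0, jitterFrac = 0.05,
                           sdlog = 0.35, s0 = 4.0, k = 0.6) {
  fieldSize <- as.integer(fieldSize)
  if (length(fieldSize) != 2L || any(fieldSize < 1L))
    stop("fieldSize must be two positive pixel counts", call. = FALSE)
  spacing <- coneSpacing(eccentricityDeg, s0 = s0, k = k)
  wUm <- fieldSize[1L] * pixelScale
  hUm <- fieldSize[2L] * pixelScale
  if (wUm < spacing / 2 || hUm < spacing / 2)
    stop("field too small to contain a cone", call. = FALSE)

  withSeed(seed, {
    # hexagonal lattice: row pitch spacing * sqrt(3)/2, odd rows offset
    rowPitch <- spacing * sqrt(3) / 2
    rows <- seq(0, hUm, by = rowPitch)
    pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      off <- if (i %% 2L == 0L) spacing / 2 else 0
      xs <- seq(off, wUm, by = spacing)
      cbind(x = xs, y = rows[i])
    }))
    jit <- matrix(stats::rnorm(length(pts), sd = jitterFrac * spacing),
                  ncol = 2L)
    pts <- pts + jit
    # keep centres on the pixel-centre grid [0, (n-1) * pixelScale]
    keep <- pts[, 1L] >= 0 & pts[, 1L] <= wUm - pixelScale &
            pts[, 2L] >= 0 & pts[, 2L] <= hUm - pixelScale
    pts <- pts[keep, , drop = FALSE]
    # drop the later member of any pair closer than half a spacing; a
    # vectorised cell list keeps this linear in the number of cones
    if (nrow(pts) > 1L) {
      thr <- 0.5 * spacing
      cx <- as.integer(floor(pts[, 1L] / thr))
      cy <- as.integer(floor(pts[, 2L] / thr))
      nx <- max(cx) - min(cx) + 3L
      key <- (cx - min(cx) + 1L) + nx * (cy - min(cy) + 1L)
      b <- split(seq_len(nrow(pts)), key)
      bk <- as.integer(names(b))
      candI <- integer(); candJ <- integer()
      for (dy in -1:1) {
        for (dx in -1:1) {
          bi <- match(key + dx + nx * dy, bk)
          has <- which(!is.na(bi))
          js <- b[bi[has]]
          ii <- rep(has, lengths(js))
          jj <- unlist(js, use.names = FALSE)
          keep <- jj > ii
          candI <- c(candI, ii[keep])
          candJ <- c(candJ, jj[keep])
        }
      }
      if (length(candI)) {
        d2 <- (pts[candI, 1L] - pts[candJ, 1L])^2 +
              (pts[candI, 2L] - pts[candJ, 2L])^2
        viol <- d2 < thr^2
        if (any(viol)) {
          vi <- candI[viol]; vj <- candJ[viol]
          drop <- logical(nrow(pts))
          for (r in order(vi, vj)) if (!drop[vi[r]]) drop[vj[r]] <- TRUE
          pts <- pts[!drop, , drop = FALSE]
        }
      }
    }
    refl <- stats::rlnorm(nrow(pts), meanlog = 0, sdlog = sdlog)
    new("ConeMosaic",
        eccentricity = as.numeric(eccentricityDeg),
        centres = unname(pts), coneWidth = 0.8 * spacing,
        reflectivities = refl, fieldSize = fieldSize,
        pixelScale = pixelScale, seed = as.integer(seed))
  })
}

#' Render the pre-optics reflectance scene of a mosaic
#'
#' Each cone is drawn as a radially symmetric truncated Gaussian of full
#' width at half maximum equal to the cone width, scaled by its
#' reflectivity, on a zero background. Overlapping profiles add linearly;
#' the result is the ideal scene before diffraction, aberration and noise.
#'
#' @param mosaic a [ConeMosaic-class]
#' @param truncFactor truncation radius as a multiple of the cone width
#' @return numeric matrix (rows = y, cols = x) of size fieldSize
#' @examples
#' sc <- renderScene(generateMosaic(5, c(64L, 64L), seed = 2))
#' dim(sc)
#' @export
renderScene <- function(mosaic, truncFactor = 1.0) {
  stopifnot(is(mosaic, "ConeMosaic"))
  w <- mosaic@fieldSize[1L]; h <- mosaic@fieldSize[2L]
  img <- matrix(0, nrow = h, ncol = w)
  n <- nrow(mosaic@centres)
  if (n == 0L) return(img)
  widthPx <- mosaic@coneWidth / mosaic@pixelScale
  sigma <- widthPx / (2 * sqrt(2 * log(2)))   # FWHM -> sd
  rad <- truncFactor * widthPx
  cx <- mosaic@centres[, 1L] / mosaic@pixelScale   # 0-based px coords
  cy <- mosaic@centres[, 2L] / mosaic@pixelScale
  for (i in seq_len(n)) {
    x0 <- max(0L, floor(cx[i] - rad)); x1 <- min(w - 1L, ceiling(cx[i] + rad))
    y0 <- max(0L, floor(cy[i] - rad)); y1 <- min(h - 1L, ceiling(cy[i] + rad))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    r2 <- outer((ys - cy[i])^2, (xs - cx[i])^2, `+`)
    g <- exp(-r2 / (2 * sigma^2))
    g[r2 > rad^2] <- 0
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
      mosaic@reflectivities[i] * g
  }
  img
}

#' Write mosaic ground truth as CSV
#'
#' Columns `x_px`, `y_px` (0-based pixel coordinates, x = column, y = row)
#' and `reflectivity`.
#'
#' @param mosaic a [ConeMosaic-class]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeGroundTruth <- function(mosaic, path) {
  df <- data.frame(
    x_px = mosaic@centres[, 1L] / mosaic@pixelScale,
    y_px = mosaic@centres[, 2L] / mosaic@pixelScale,
    reflectivity = mosaic@reflectivities)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cone-centre annotations from CSV
#'
#' Expects columns `x_px`, `y_px` (0-based); extra columns are ignored.
#'
#' @param path CSV path
#' @return n x 2 matrix of (x, y) pixel coordinates
#' @export
readGroundTruth <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df)))
    stop("annotation CSV needs columns x_px, y_px", call. = FALSE)
  unname(as.matrix(df[, c("x_px", "y_px")]))
}
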