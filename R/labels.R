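#' Build a Gaussian ground-truth label map
#'
#' Each cone centre contributes an isotropic Gaussian (sd =
#' `coneWidthPx / 4` by default) truncated at one cone radius
#' (`coneWidthPx / 2`), evaluated per cone as in a Z-stack; overlapping
#' contributions are combined by maximum-intensity projection, not summed,
#' and the result is scaled so its maximum is 255.
#'
#' @param centres n x 2 matrix of (x, y) 0-based pixel coordinates
#' @param coneWidthPx cone width in pixels (> 0)
#' @param shape integer c(width, height) of the map in pixels
#' @param sigmaPx Gaussian sd; default `coneWidthPx / 4`
#' @return a [LabelMap-class]
#' @examples
#' lm <- makeLabelMap(cbind(10, 12), 6, c(32L, 32L))
#' max(mapValues(lm))
#' @export
makeLabelMap <- function(centres, coneWidthPx, shape,
                         sigmaPx = coneWidthPx / 4) {
  if (coneWidthPx <= 0) stop("coneWidthPx must be > 0", call. = FALSE)
  w <- as.integer(shape[1L]); h <- as.integer(shape[2L])
  vals <- matrix(0, h, w)
  rad <- coneWidthPx / 2
  if (length(centres) && nrow(centres)) {
    inb <- centres[, 1L] >= 0 & centres[, 1L] <= w - 1L &
           centres[, 2L] >= 0 & centres[, 2L] <= h - 1L
    if (any(!inb))
      warning(sum(!inb), " centre(s) outside the map were dropped")
    centres <- centres[inb, , drop = FALSE]
    for (i in seq_len(nrow(centres))) {
      cx <- centres[i, 1L]; cy <- centres[i, 2L]
      x0 <- max(0L, floor(cx - rad)); x1 <- min(w - 1L, ceiling(cx + rad))
      y0 <- max(0L, floor(cy - rad)); y1 <- min(h - 1L, ceiling(cy + rad))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      r2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      g <- exp(-r2 / (2 * sigmaPx^2))
      g[r2 > rad^2] <- 0
      blk <- vals[ys + 1L, xs + 1L, drop = FALSE]
      vals[ys + 1L, xs + 1L] <- pmax(blk, g)
    }
    if (max(vals) > 0) vals <- vals * (255 / max(vals))
  }
  new("LabelMap", values = vals, sigmaPx = sigmaPx, truncationRadiusPx = rad)
}

#' Tile a full image (and its annotations) into non-overlapping crops
#'
#' Lays a `grid\[1\]` x `grid\[2\]` grid of equal tiles over the image and
#' centre-crops each tile to `cropSize` x `cropSize`, giving pairwise
#' disjoint crops: a 480 x 300 image yields 12 tiles of 120 x 100, each
#' centre-cropped to 96 x 96. Cone centres are re-expressed in local crop
#' coordinates; label maps are cropped with the same windows.
#'
#' @param image numeric matrix (rows = y)
#' @param centres optional n x 2 (x, y) 0-based global coordinates
#' @param label optional [LabelMap-class] aligned with `image`
#' @param grid integer c(columns, rows) of tiles
#' @param cropSize crop side in pixels
#' @return list of crops, each a list with `image`, `offset` (0-based
#'   c(x0, y0)), and where supplied `centres` (local) and `label`
#' @export
tileImage <- function(image, centres = NULL, label = NULL,
                      grid = c(4L, 3L), cropSize = 96L) {
  stopIfNot2D(image)
  H <- nrow(image); W <- ncol(image)
  tw <- W %/% grid[1L]; th <- H %/% grid[2L]
  if (tw < cropSize || th < cropSize)
    stop(sprintf("image %d x %d too small for a %d x %d grid of %d px crops",
                 W, H, grid[1L], grid[2L], cropSize), call. = FALSE)
  out <- vector("list", grid[1L] * grid[2L])
  k <- 0L
  for (r in seq_len(grid[2L]) - 1L) {
    for (cc in seq_len(grid[1L]) - 1L) {
      x0 <- cc * tw + (tw - cropSize) %/% 2L
      y0 <- r * th + (th - cropSize) %/% 2L
      crop <- list(
        image = image[(y0 + 1L):(y0 + cropSize), (x0 + 1L):(x0 + cropSize)],
        offset = c(x0, y0))
      if (!is.null(centres)) {
        loc <- cbind(centres[, 1L] - x0, centres[, 2L] - y0)
        keep <- loc[, 1L] >= 0 & loc[, 1L] <= cropSize - 1L &
                loc[, 2L] >= 0 & loc[, 2L] <= cropSize - 1L
        crop$centres <- loc[keep, , drop = FALSE]
      }
      if (!is.null(label)) {
        crop$label <- new("LabelMap",
          values = label@values[(y0 + 1L):(y0 + cropSize),
                                (x0 + 1L):(x0 + cropSize)],
          sigmaPx = label@sigmaPx,
          truncationRadiusPx = label@truncationRadiusPx)
      }
      k <- k + 1L
      out[[k]] <- crop
    }
  }
  out
}

# Bilinear sampler with reflect boundary; coords are 0-based (x, y).
bilinearSample <- function(img, xs, ys) {
  H <- nrow(img); W <- ncol(img)
  reflect <- function(v, n) {
    # reflect about pixel centres into [0, n-1]
    v <- abs(v)
    p <- 2 * (n - 1)
    v <- v %% p
    ifelse(v > n - 1, p - v, v)
  }
  xs <- reflect(xs, W); ys <- reflect(ys, H)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  idx <- function(yy, xx) img[cbind(yy + 1L, xx + 1L)]
  (1 - fy) * ((1 - fx) * idx(y0, x0) + fx * idx(y0, x1)) +
    fy * ((1 - fx) * idx(y1, x0) + fx * idx(y1, x1))
}

#' Rotate an image about its centre
#'
#' Bilinear resampling with reflect fill; output has the input's size.
#'
#' @param img numeric matrix
#' @param angleDeg rotation angle, degrees counter-clockwise
#' @return rotated matrix
#' @export
rotateImage <- function(img, angleDeg) {
  if (angleDeg %% 360 == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  a <- angleDeg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  gx <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
  gy <- matrix(0:(H - 1), H, W) - cy
  # inverse map: rotate output grid by -angle
  sx <- cos(-a) * gx - sin(-a) * gy + cx
  sy <- sin(-a) * gx + cos(-a) * gy + cy
  matrix(bilinearSample(img, as.vector(sx), as.vector(sy)), H, W)
}

# Transform 0-based centres by rotation about image centre then optional
# y-flip, matching rotateImage / flip on an H x W image.
transformCentres <- function(centres, angleDeg, flip, W, H) {
  if (!length(centres) || !nrow(centres)) return(centres)
  a <- angleDeg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  x <- centres[, 1L] - cx; y <- centres[, 2L] - cy
  xr <- cos(a) * x - sin(a) * y + cx
  yr <- sin(a) * x + cos(a) * y + cy
  if (flip) yr <- (H - 1) - yr
  cbind(xr, yr)
}

#' Augment a crop by rotation and x-axis flipping
#'
#' Produces `factor` variants as (rotation angle, flip) pairs: angles are
#' evenly spaced over [0, 360) and each is used with and without a flip
#' along the x-axis, so a factor of 200 means 100 angles x 2 flip states.
#' The image, the label map and the centres all receive the identical
#' transform; the first variant is always the untransformed original.
#'
#' @param image numeric crop
#' @param label optional [LabelMap-class]
#' @param centres optional n x 2 local (x, y) coordinates
#' @param factor number of variants to produce (>= 1)
#' @param seed kept for API symmetry; the enumeration is deterministic
#' @return list of `factor` lists with elements `image`, `angle`, `flip`
#'   and, where supplied, `label` and `centres`
#' @export
augmentCrop <- function(image, label = NULL, centres = NULL,
                        factor = 1L, seed = 1L) {
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  nAng <- as.integer(ceiling(factor / 2))
  angles <- (seq_len(nAng) - 1L) * 360 / nAng
  out <- vector("list", factor)
  for (k in seq_len(factor)) {
    flip <- (k - 1L) %% 2L == 1L
    ang <- angles[(k - 1L) %/% 2L + 1L]
    img <- rotateImage(image, ang)
    if (flip) img <- img[H:1, , drop = FALSE]
    v <- list(image = img, angle = ang, flip = flip)
    if (!is.null(label)) {
      lv <- rotateImage(label@values, ang)
      if (flip) lv <- lv[H:1, , drop = FALSE]
      v$label <- new("LabelMap", values = clip01(lv, 0, 255),
                     sigmaPx = label@sigmaPx,
                     truncationRadiusPx = label@truncationRadiusPx)
    }
    if (!is.null(centres))
      v$centres <- transformCentres(centres, ang, flip, W, H)
    out[[k]] <- v
  }
  out
}
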