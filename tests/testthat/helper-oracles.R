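# Independent oracles used across the suite. Each reimplements the quantity
# it checks from first principles, sharing no code with the package paths.

# Brute-force one-to-one matcher: enumerate all candidate pairs within the
# distance bound, scan them in globally ascending (distance, predicted,
# truth) order, accept a pair when both ends are unused.
oracleMatch <- function(pred, truth, maxDist) {
  np <- nrow(pred); nt <- nrow(truth)
  cand <- NULL
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      d <- sqrt(sum((pred[i, ] - truth[j, ])^2))
      if (d <= maxDist) cand <- rbind(cand, c(i, j, d))
    }
  }
  if (is.null(cand))
    return(list(pairs = matrix(0, 0L, 2L), tp = 0L, fp = np, fn = nt))
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  usedP <- logical(np); usedT <- logical(nt); sel <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!usedP[i] && !usedT[j]) {
      usedP[i] <- TRUE; usedT[j] <- TRUE
      sel <- rbind(sel, cand[r, 1:2])
    }
  }
  list(pairs = sel, tp = nrow(sel), fp = np - nrow(sel), fn = nt - nrow(sel))
}

# Per-cone truncated-Gaussian stack with explicit max projection.
oracleLabelMap <- function(centres, widthPx, shape, sigma = widthPx / 4) {
  w <- shape[1]; h <- shape[2]
  rad <- widthPx / 2
  stack <- array(0, c(h, w, max(1L, nrow(centres))))
  for (i in seq_len(nrow(centres))) {
    for (yy in 0:(h - 1)) {
      for (xx in 0:(w - 1)) {
        r2 <- (xx - centres[i, 1])^2 + (yy - centres[i, 2])^2
        if (r2 <= rad^2) stack[yy + 1, xx + 1, i] <- exp(-r2 / (2 * sigma^2))
      }
    }
  }
  m <- apply(stack, c(1, 2), max)
  if (max(m) > 0) m <- m * 255 / max(m)
  m
}

# Direct O(N^2) spatial convolution with reflect padding ("same" output).
oracleConvolve <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  h2 <- (kh - 1) %/% 2; w2 <- (kw - 1) %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (r in 1:H) {
    for (cc in 1:W) {
      s <- 0
      for (a in 1:kh) {
        for (b in 1:kw) {
          # convolution: kernel flipped relative to correlation
          sr <- refl(r - (a - h2 - 1), H)
          sc <- refl(cc - (b - w2 - 1), W)
          s <- s + x[sr, sc] * k[a, b]
        }
      }
      out[r, cc] <- s
    }
  }
  out
}

# Small synthetic crop set for training tests: simulated combined-condition
# images tiled with labels. Cached so expensive fixtures build once.
.fixtures <- new.env()

fixtureCrops <- function(nImages = 6L, eccs = c(3, 6), seed = 11L) {
  key <- paste0("crops_", nImages, "_", paste(eccs, collapse = "."), "_", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  psf <- psfFromWavefront(wavefront(numeric(1), 0L), opticsSpec())
  crops <- list()
  per <- ceiling(nImages / length(eccs))
  n <- 0L
  for (e in eccs) {
    for (i in seq_len(per)) {
      if (n >= nImages) break
      n <- n + 1L
      s <- seed + 97L * n
      m <- generateMosaic(e, c(480L, 300L), seed = s)
      img <- acquireImage(applyOptics(renderScene(m), psf),
                          acquisitionConfig(seed = s))
      cen <- coneCentres(m)
      lab <- makeLabelMap(cen, 0.8 * coneSpacing(e), c(480L, 300L))
      crops <- c(crops, lapply(tileImage(img, centres = cen, label = lab),
                               function(cr) {
                                 cr$coneWidthPx <- 0.8 * coneSpacing(e)
                                 cr
                               }))
    }
  }
  .fixtures[[key]] <- crops
  crops
}

# A briefly trained tiny model over the fixture crops (not accurate, but
# produces structured probability maps for detection/tuning tests).
fixtureModel <- function(epochs = 2L) {
  key <- paste0("model_", epochs)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  crops <- fixtureCrops()
  net <- buildNetwork(tinyNetworkConfig(), seed = 21L)
  arr <- cropsToArrays(crops[1:60])
  val <- cropsToArrays(crops[61:72])
  trainNetwork(net, arr, val,
               trainingSchedule(maxEpochs = epochs, batchSize = 16L),
               seed = 3L)
  .fixtures[[key]] <- net
  net
}
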