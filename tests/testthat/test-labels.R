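test_that("label maps are max-projected truncated Gaussians scaled to 255", {
  cen <- cbind(c(12, 13, 30), c(10, 10, 25))
  lm <- makeLabelMap(cen, 8, c(40L, 36L))
  v <- mapValues(lm)
  expect_equal(max(v), 255)
  expect_true(all(v >= 0))
  # zero outside every truncation radius
  for (yy in 0:35) for (xx in 0:39) {
    if (all((xx - cen[, 1])^2 + (yy - cen[, 2])^2 > 16)) {
      expect_identical(v[yy + 1, xx + 1], 0)
      break
    }
  }
  expect_equal(v, oracleLabelMap(cen, 8, c(40L, 36L)), tolerance = 1e-9)
})

test_that("overlapping Gaussians take the max, never the sum", {
  cen <- cbind(c(20, 21), c(15, 15))
  v <- mapValues(makeLabelMap(cen, 8, c(40L, 30L)))
  expect_equal(v, oracleLabelMap(cen, 8, c(40L, 30L)), tolerance = 1e-9)
  # between the two centres the value never exceeds a single peak
  expect_lte(max(v), 255)
})

test_that("label construction handles empty and out-of-map centres", {
  empty <- makeLabelMap(matrix(numeric(), 0L, 2L), 6, c(20L, 20L))
  expect_true(all(mapValues(empty) == 0))
  expect_warning(lm <- makeLabelMap(cbind(c(5, 99), c(5, 99)), 6,
                                    c(20L, 20L)), "dropped")
  expect_equal(mapValues(lm), oracleLabelMap(cbind(5, 5), 6, c(20L, 20L)),
               tolerance = 1e-9)
  expect_error(makeLabelMap(cbind(1, 1), 0, c(10L, 10L)), "coneWidthPx")
})

test_that("label invariants hold across random mosaics", {
  for (seed in 1:3) {
    m <- generateMosaic(6, c(60L, 50L), seed = seed)
    cen <- coneCentres(m)
    w <- coneWidth(m)
    lm <- makeLabelMap(cen, w, c(60L, 50L))
    v <- mapValues(lm)
    expect_equal(max(v), 255)
    expect_true(all(v >= 0 & v <= 255))
    far <- matrix(TRUE, 50, 60)
    for (i in seq_len(nrow(cen))) {
      r2 <- outer((0:49 - cen[i, 2])^2, (0:59 - cen[i, 1])^2, `+`)
      far <- far & (r2 > (w / 2)^2)
    }
    expect_true(all(v[far] == 0))
  }
})

test_that("tiling produces 12 disjoint 96x96 crops with exact coordinates", {
  img <- matrix(seq_len(480 * 300), 300, 480)
  cen <- cbind(c(10, 130, 470), c(10, 150, 290))
  crops <- tileImage(img, centres = cen)
  expect_length(crops, 12)
  covered <- matrix(0L, 300, 480)
  for (cr in crops) {
    expect_identical(dim(cr$image), c(96L, 96L))
    x0 <- cr$offset[1]; y0 <- cr$offset[2]
    covered[y0 + 1:96, x0 + 1:96] <- covered[y0 + 1:96, x0 + 1:96] + 1L
    expect_equal(cr$image, img[y0 + 1:96, x0 + 1:96])
    # inverse coordinate mapping round-trips
    if (nrow(cr$centres)) {
      glob <- sweep(cr$centres, 2, cr$offset, `+`)
      expect_true(all(apply(glob, 1, function(g)
        any(abs(cen[, 1] - g[1]) < 1e-9 & abs(cen[, 2] - g[2]) < 1e-9))))
    }
  }
  expect_lte(max(covered), 1L)   # pairwise disjoint
  # a cone at global (10, 10) appears only in crop 1 at (10 - 12, 10 - 2)?
  # offsets are (12, 2): 10 < 12, so it falls in no crop; use (20, 20)
  crops2 <- tileImage(img, centres = cbind(20, 20))
  hits <- which(vapply(crops2, function(cr) nrow(cr$centres) > 0, logical(1)))
  expect_identical(hits, 1L)
  expect_equal(crops2[[1]]$centres, cbind(20 - 12, 20 - 2))
  expect_error(tileImage(matrix(0, 100, 100)), "too small")
})

test_that("tiling crops label maps with the image windows", {
  m <- generateMosaic(4, c(480L, 300L), seed = 3)
  cen <- coneCentres(m)
  lab <- makeLabelMap(cen, coneWidth(m), c(480L, 300L))
  crops <- tileImage(renderScene(m), centres = cen, label = lab)
  cr <- crops[[7]]
  x0 <- cr$offset[1]; y0 <- cr$offset[2]
  expect_equal(mapValues(cr$label), mapValues(lab)[y0 + 1:96, x0 + 1:96])
})

test_that("augmentation enumerates rotation/flip pairs deterministically", {
  set.seed(31)
  img <- matrix(runif(96 * 96), 96, 96)
  cen <- cbind(c(30, 60, 48), c(40, 20, 48))
  lab <- makeLabelMap(cen, 8, c(96L, 96L))
  one <- augmentCrop(img, lab, cen, factor = 1L)
  expect_length(one, 1)
  expect_identical(one[[1]]$image, img)
  expect_equal(unname(one[[1]]$centres), unname(cen + 0))

  aug <- augmentCrop(img, lab, cen, factor = 8L)
  expect_length(aug, 8)
  angles <- vapply(aug, function(a) a$angle, numeric(1))
  flips <- vapply(aug, function(a) a$flip, logical(1))
  expect_equal(sort(unique(angles)), c(0, 90, 180, 270))
  expect_equal(sum(flips), 4L)
  # flip applied twice is the identity
  flipped <- aug[[2]]$image
  expect_identical(flipped[96:1, ], img)
  # interior cone count is preserved by every transform
  for (a in aug) {
    inside <- a$centres[, 1] >= 0 & a$centres[, 1] <= 95 &
              a$centres[, 2] >= 0 & a$centres[, 2] <= 95
    expect_equal(sum(inside), nrow(cen))
  }
  # the same call reproduces identical output
  aug2 <- augmentCrop(img, lab, cen, factor = 8L)
  expect_identical(aug, aug2)
})

test_that("rotation moves centres consistently with the image", {
  img <- matrix(0, 96, 96)
  img[41, 61] <- 1   # cone at x = 60, y = 40
  aug <- augmentCrop(img, centres = cbind(60, 40), factor = 4L)
  for (a in aug) {
    pk <- which(a$image == max(a$image), arr.ind = TRUE)
    expect_lt(abs(pk[1, 2] - 1 - a$centres[1, 1]), 1.0)
    expect_lt(abs(pk[1, 1] - 1 - a$centres[1, 2]), 1.0)
  }
})
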