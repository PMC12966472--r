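test_that("cone spacing is the configured linear model and stays plausible", {
  expect_equal(coneSpacing(5), 7.0)
  e <- seq(1, 10, by = 0.5)
  s <- coneSpacing(e)
  expect_true(all(diff(s) > 0))
  expect_gt(coneSpacing(10), coneSpacing(1))
  expect_true(all(s > 2 & s < 20))
  expect_error(coneSpacing(0), "eccentricity")
  expect_error(coneSpacing(10.5), "eccentricity")
})

test_that("mosaic generation is deterministic and seed-sensitive", {
  a <- generateMosaic(3, c(200L, 150L), seed = 4)
  b <- generateMosaic(3, c(200L, 150L), seed = 4)
  expect_identical(coneCentres(a), coneCentres(b))
  expect_identical(reflectivities(a), reflectivities(b))
  c2 <- generateMosaic(3, c(200L, 150L), seed = 5)
  expect_false(identical(reflectivities(a), reflectivities(c2)))
  expect_error(generateMosaic(3, c(0L, 10L)), "fieldSize")
})

test_that("cone count matches hexagonal packing density within 20%", {
  for (e in c(1, 5, 10)) {
    m <- generateMosaic(e, c(480L, 300L), seed = e)
    s <- coneSpacing(e)
    expected <- 480 * 300 / (sqrt(3) / 2 * s^2)
    expect_lt(abs(nrow(coneCentres(m)) / expected - 1), 0.2)
  }
})

test_that("mosaic respects separation and boundary invariants", {
  for (seed in 1:3) {
    m <- generateMosaic(2, c(300L, 200L), seed = seed)
    p <- coneCentres(m)
    expect_true(all(p[, 1] >= 0 & p[, 1] <= 299 & p[, 2] >= 0 & p[, 2] <= 199))
    d <- stats::dist(p)
    expect_gte(min(d), 0.5 * coneSpacing(2))
    expect_true(all(reflectivities(m) > 0))
  }
})

test_that("mean nearest-neighbour distance tracks the spacing model", {
  for (e in c(2, 7)) {
    m <- generateMosaic(e, c(480L, 300L), seed = 30 + e)
    p <- coneCentres(m)
    expect_gt(nrow(p), 100)
    dm <- as.matrix(stats::dist(p))
    diag(dm) <- Inf
    nnd <- apply(dm, 1, min)
    expect_lt(abs(mean(nnd) / coneSpacing(e) - 1), 0.1)
  }
})

test_that("rendered scenes are linear in reflectivity and conserve flux", {
  m <- generateMosaic(5, c(200L, 150L), seed = 7)
  sc <- renderScene(m)
  expect_identical(dim(sc), c(150L, 200L))
  m2 <- m
  m2@reflectivities <- 2 * m@reflectivities
  expect_equal(renderScene(m2), 2 * sc)
  # total intensity equals the sum of per-cone truncated-profile integrals
  # (cones kept clear of the borders so no profile is cut by the frame)
  widthPx <- coneWidth(m) / m@pixelScale
  keep <- m@centres[, 1] > widthPx & m@centres[, 1] < 200 - widthPx &
          m@centres[, 2] > widthPx & m@centres[, 2] < 150 - widthPx
  mi <- m
  mi@centres <- m@centres[keep, , drop = FALSE]
  mi@reflectivities <- m@reflectivities[keep]
  one <- m
  one@centres <- matrix(c(100, 75), 1)
  one@reflectivities <- 1
  unitIntegral <- sum(renderScene(one))
  expect_lt(abs(sum(renderScene(mi)) /
                (unitIntegral * sum(mi@reflectivities)) - 1), 0.01)
})

test_that("single-cone scene peaks at the cone with height proportional to r", {
  m <- generateMosaic(5, c(64L, 64L), seed = 1)
  m@centres <- matrix(c(30, 22), 1)
  m@reflectivities <- 1.7
  sc <- renderScene(m)
  pk <- which(sc == max(sc), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(23, 31))   # row = y + 1, col = x + 1
  expect_equal(max(sc), 1.7)
  m@centres <- matrix(numeric(), 0L, 2L)
  m@reflectivities <- numeric()
  expect_true(all(renderScene(m) == 0))
})

test_that("ground truth round-trips through CSV", {
  m <- generateMosaic(4, c(100L, 80L), seed = 2)
  f <- tempfile(fileext = ".csv")
  writeGroundTruth(m, f)
  got <- readGroundTruth(f)
  expect_equal(got, coneCentres(m) / m@pixelScale, tolerance = 1e-12)
  unlink(f)
})
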