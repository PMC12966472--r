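test_that("Zernike time-series averaging matches a direct mean", {
  expect_equal(meanZernikeOverTime(list(`3` = c(0.2, 0.2, 0.2)))@coefficients,
               0.2)
  expect_equal(meanZernikeOverTime(list(`4` = c(1, -1)))@coefficients, 0)
  set.seed(8)
  df <- data.frame(mode_index = rep(3:8, each = 20),
                   coefficient_um = rnorm(120))
  wf <- meanZernikeOverTime(df)
  ref <- vapply(3:8, function(j)
    mean(df$coefficient_um[df$mode_index == j]), numeric(1))
  expect_equal(wf@coefficients, ref)
  expect_equal(wf@amplitudeFraction, 1)
  expect_error(meanZernikeOverTime(df[0, ]), "empty")
})

test_that("lowest-RMS eye selection agrees with an exhaustive sort", {
  set.seed(9)
  eyes <- lapply(1:10, function(i)
    wavefront(rnorm(12, sd = 0.1), 3:14, eyeId = paste0("e", i)))
  rms <- vapply(eyes, wavefrontRMS, numeric(1), scaled = FALSE)
  sel <- selectLowestRmsEyes(eyes, 4)
  expect_identical(vapply(sel, function(w) w@eyeId, character(1)),
                   vapply(eyes[order(rms)][1:4], function(w) w@eyeId,
                          character(1)))
  all10 <- selectLowestRmsEyes(eyes, 10)
  expect_identical(vapply(all10, wavefrontRMS, numeric(1), scaled = FALSE),
                   sort(rms))
  expect_error(selectLowestRmsEyes(eyes, 11), "exceeds")
})

test_that("amplitude fraction scales the wavefront RMS exactly", {
  wf <- wavefront(c(0, 0, 0, 0.1, -0.05, 0.02), 0:5)
  for (f in c(0.1, 0.2, 0.3, 1)) {
    scaled <- setAmplitudeFraction(wf, f)
    expect_equal(wavefrontRMS(scaled), f * wavefrontRMS(wf, scaled = FALSE),
                 tolerance = 1e-9)
  }
  expect_error(setAmplitudeFraction(wf, 0), "amplitudeFraction")
})

test_that("diffraction-limited PSF reproduces the Airy pattern", {
  opt <- opticsSpec(pixelScaleUm = 0.25, pupilGridSize = 2048L)
  psf <- psfFromWavefront(wavefront(numeric(1), 0L), opt)
  k <- kernelMatrix(psf)
  expect_true(all(k >= 0))
  expect_lt(abs(sum(k) - 1), 1e-6)
  # first minimum of the radial profile vs 1.22 lambda/D on the retina
  c0 <- (nrow(k) + 1) %/% 2
  prof <- k[c0, c0:ncol(k)]
  i <- which(diff(prof) > 0)[1]
  measured <- (i - 1) * 0.25
  analytic <- 1.22 * (850e-9 / 5e-3) * 17e3  # um on the retina (f = 17 mm)
  expect_lt(abs(measured / analytic - 1), 0.02)
})

test_that("Strehl ratio is 1 unaberrated and degrades with amplitude", {
  opt <- opticsSpec()
  expect_equal(strehlRatio(wavefront(numeric(1), 0L), opt), 1.0)
  wf <- wavefront(c(0.08, -0.05, 0.04, 0.03, -0.02, 0.02, 0.05, 0.01,
                    -0.03, 0.02, 0.01, -0.01), 3:14)
  s <- vapply(c(0.1, 0.2, 0.3), function(f)
    strehlRatio(setAmplitudeFraction(wf, f), opt), numeric(1))
  expect_true(all(diff(s) <= 1e-9))
  expect_lt(s[3], 1)
})

test_that("PSFs stay nonnegative and unit-sum across random wavefronts", {
  opt <- opticsSpec()
  set.seed(12)
  for (r in 1:4) {
    wf <- wavefront(rnorm(12, sd = 0.05), 3:14,
                    amplitudeFraction = sample(c(0.1, 0.2, 0.3), 1))
    k <- kernelMatrix(psfFromWavefront(wf, opt))
    expect_true(all(k >= 0))
    expect_lt(abs(sum(k) - 1), 1e-6)
  }
})

test_that("pupil sampling and Nyquist guards fire", {
  expect_error(psfFromWavefront(wavefront(numeric(1), 0L),
                                opticsSpec(pupilGridSize = 128L,
                                           pixelScaleUm = 0.2)),
               "64")
  expect_warning(psfFromWavefront(wavefront(numeric(1), 0L),
                                  opticsSpec(pixelScaleUm = 2.0)),
                 "undersamples")
})

test_that("optical blur matches a direct spatial convolution", {
  set.seed(13)
  scene <- matrix(runif(16 * 16), 16, 16)
  k <- matrix(runif(25), 5, 5)
  k <- k / sum(k)
  psf <- new("PSF", kernel = k, pixelScaleUm = 1.0)
  got <- applyOptics(scene, psf)
  expect_equal(got, oracleConvolve(scene, k), tolerance = 1e-10)
})

test_that("delta scenes return the kernel; identity kernels return the scene", {
  k <- matrix(runif(9), 3, 3); k <- k / sum(k)
  psf <- new("PSF", kernel = k, pixelScaleUm = 1.0)
  delta <- matrix(0, 9, 9); delta[5, 5] <- 1
  out <- applyOptics(delta, psf)
  expect_equal(out[4:6, 4:6], k, tolerance = 1e-12)
  idn <- new("PSF", kernel = matrix(1, 1, 1), pixelScaleUm = 1.0)
  sc <- matrix(rnorm(64), 8, 8)
  expect_equal(applyOptics(sc, idn), sc, tolerance = 1e-12)
  expect_error(applyOptics(sc, psf, pixelScale = 2), "pixel scales")
  # intensity conserved within 1% under reflect padding
  m <- generateMosaic(5, c(120L, 100L), seed = 3)
  sc2 <- renderScene(m)
  expect_lt(abs(sum(applyOptics(sc2, psf)) / sum(sc2) - 1), 0.01)
})

test_that("synthetic Zernike series behave like a measured panel", {
  ser <- syntheticZernikeSeries(nEyes = 5, nTime = 30, seed = 2)
  expect_setequal(unique(ser$eye_id), sprintf("eye%02d", 1:5))
  eyes <- wavefrontsFromSeries(ser)
  expect_length(eyes, 5)
  expect_true(all(vapply(eyes, wavefrontRMS, numeric(1), scaled = FALSE) > 0))
  ser2 <- syntheticZernikeSeries(nEyes = 5, nTime = 30, seed = 2)
  expect_identical(ser, ser2)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(ser, f, row.names = FALSE)
  expect_equal(nrow(readZernikeCSV(f)), nrow(ser))
  unlink(f)
})
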