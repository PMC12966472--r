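test_that("identical interior point sets match perfectly", {
  set.seed(1)
  pts <- cbind(runif(20, 20, 70), runif(20, 20, 70))
  m <- matchCones(pts, pts, coneWidthPx = 6, chi = 0.75,
                  imageShape = c(96L, 96L))
  expect_equal(m@tp, 20L)
  expect_equal(m@fp, 0L)
  expect_equal(m@fn, 0L)
  expect_true(all(m@pairs$distance == 0))
})

test_that("the closer of two competing predictions wins the pair", {
  truth <- cbind(50, 50)
  pred <- rbind(c(51, 50), c(52, 50))   # 1 px and 2 px away
  m <- matchCones(pred, truth, coneWidthPx = 6, chi = 0.75,
                  imageShape = c(96L, 96L))
  expect_equal(m@tp, 1L)
  expect_equal(m@fp, 1L)
  expect_equal(m@fn, 0L)
  expect_equal(m@pairs$predicted, 1L)
  expect_equal(m@pairs$distance, 1)
})

test_that("edge cones are excluded strictly within the margin", {
  w <- 6; chi <- 0.5                    # margin = 3 px
  truth <- rbind(c(3, 50), c(2.9, 50), c(92, 50), c(92.2, 50))
  m <- matchCones(truth, truth, w, chi, c(96L, 96L))
  # x = 3 and x = 92 sit exactly on the margin boundary: retained
  expect_equal(m@tp, 2L)
  expect_equal(m@fn, 0L)
  expect_equal(m@fp, 0L)
})

test_that("empty inputs are valid and produce zero counts", {
  m <- matchCones(matrix(0, 0, 2), matrix(0, 0, 2), 6, 0.75, c(96L, 96L))
  expect_equal(c(m@tp, m@fp, m@fn), c(0L, 0L, 0L))
  met <- computeMetrics(m)
  expect_equal(met@dice, 1)
  expect_equal(met@tpr, 1)
  expect_equal(met@fdr, 0)
})

test_that("matching agrees exactly with the brute-force oracle", {
  set.seed(7)
  for (trial in 1:200) {
    np <- sample(0:50, 1); nt <- sample(0:50, 1)
    shape <- c(60L, 60L)
    w <- runif(1, 4, 8); chi <- sample(c(0.5, 0.75, 1), 1)
    margin <- chi * w
    pred <- cbind(runif(np, 0, 59), runif(np, 0, 59))
    truth <- cbind(runif(nt, 0, 59), runif(nt, 0, 59))
    m <- matchCones(pred, truth, w, chi, shape)
    keepP <- pred[, 1] >= margin & pred[, 1] <= 59 - margin &
             pred[, 2] >= margin & pred[, 2] <= 59 - margin
    keepT <- truth[, 1] >= margin & truth[, 1] <= 59 - margin &
             truth[, 2] >= margin & truth[, 2] <= 59 - margin
    o <- oracleMatch(pred[keepP, , drop = FALSE],
                     truth[keepT, , drop = FALSE], margin)
    expect_identical(c(m@tp, m@fp, m@fn), c(o$tp, as.integer(o$fp),
                                            as.integer(o$fn)))
    if (m@tp > 0) {
      got <- m@pairs[order(m@pairs$predicted), c("predicted", "truth")]
      want <- o$pairs[order(o$pairs[, 1]), , drop = FALSE]
      expect_equal(unname(as.matrix(got)), unname(want))
    }
    # invariants: one-to-one, distance bound, count accounting
    expect_lte(max(c(0, m@pairs$distance)), chi * w + 1e-9)
    expect_false(anyDuplicated(m@pairs$predicted) > 0)
    expect_false(anyDuplicated(m@pairs$truth) > 0)
    expect_equal(m@tp + m@fp, sum(keepP))
    expect_equal(m@tp + m@fn, sum(keepT))
  }
})

test_that("metric formulas reproduce hand-computed values", {
  cases <- list(
    # tp, fp, fn, dice, tpr, fdr
    c(9, 1, 1, 0.9, 0.9, 0.1),
    c(0, 0, 5, 0, 0, 0),
    c(100, 0, 0, 1, 1, 0),
    c(0, 5, 0, 0, 1, 1),
    c(1, 1, 1, 0.5, 0.5, 0.5),
    c(50, 10, 5, 100 / 115, 50 / 55, 10 / 60),
    c(3, 0, 1, 6 / 7, 0.75, 0),
    c(3, 1, 0, 6 / 7, 1, 0.25),
    c(0, 0, 0, 1, 1, 0),
    c(7, 2, 3, 14 / 19, 0.7, 2 / 9),
    c(1, 0, 0, 1, 1, 0),
    c(0, 1, 1, 0, 0, 1),
    c(20, 20, 20, 0.5, 0.5, 0.5),
    c(199, 1, 0, 398 / 399, 199 / 199, 1 / 200),
    c(985, 6, 15, 1970 / 1991, 985 / 1000, 6 / 991),
    c(12, 3, 4, 24 / 31, 0.75, 0.2),
    c(5, 5, 0, 2 / 3, 1, 0.5),
    c(5, 0, 5, 2 / 3, 0.5, 0),
    c(2, 8, 2, 4 / 14, 0.5, 0.8),
    c(60, 12, 6, 120 / 138, 60 / 66, 12 / 72))
  for (cs in cases) {
    met <- computeMetrics(cs[1], cs[2], cs[3])
    expect_equal(met@dice, cs[4], tolerance = 1e-12)
    expect_equal(met@tpr, cs[5], tolerance = 1e-12)
    expect_equal(met@fdr, cs[6], tolerance = 1e-12)
  }
  expect_error(computeMetrics(-1, 0, 0), "negative")
})

test_that("Dice is symmetric in fp/fn and monotone in errors", {
  for (tp in c(1, 10)) {
    for (a in 0:4) for (b in 0:4) {
      expect_equal(computeMetrics(tp, a, b)@dice,
                   computeMetrics(tp, b, a)@dice)
    }
    d <- vapply(0:5, function(fp) computeMetrics(tp, fp, 2)@dice, numeric(1))
    expect_true(all(diff(d) < 0))
  }
})

test_that("dataset evaluation summarises per-image metrics correctly", {
  truth1 <- cbind(runif(10, 10, 50), runif(10, 10, 50))
  dets <- list(img1 = truth1,                       # perfect
               img2 = truth1[1:8, ])                # 2 misses
  truths <- list(img1 = truth1, img2 = truth1)
  ev <- evaluateDataset(dets, truths, chi = 0.75, coneWidths = 6,
                        imageShape = c(60L, 60L))
  expect_equal(nrow(ev$perImage), 2)
  expect_equal(ev$perImage$dice[1], 1)
  # summary equals independent recomputation
  expect_equal(ev$summary$mean[ev$summary$metric == "dice"],
               mean(ev$perImage$dice))
  expect_equal(ev$summary$sd[ev$summary$metric == "dice"],
               stats::sd(ev$perImage$dice))
  # two images with dice 0.8 and 1.0: mean 0.9, sample SD ~0.1414
  fake <- list(a = cbind(c(20, 30, 40, 25), c(20, 30, 40, 35)))
  expect_error(evaluateDataset(fake, list(), 0.75, 6, c(60L, 60L)),
               "missing ground truth")
  d2 <- c(0.8, 1.0)
  expect_equal(stats::sd(d2), 0.1414, tolerance = 1e-3)
  # randomised set: summary matches recomputation from per-image values
  set.seed(11)
  dets <- list(); truths <- list()
  for (i in 1:20) {
    t0 <- cbind(runif(15, 10, 50), runif(15, 10, 50))
    p0 <- t0 + matrix(rnorm(30, 0, 2), ncol = 2)
    id <- paste0("r", i)
    dets[[id]] <- p0
    truths[[id]] <- t0
  }
  ev <- evaluateDataset(dets, truths, 0.75, 6, c(60L, 60L))
  expect_equal(ev$summary$mean,
               c(mean(ev$perImage$dice), mean(ev$perImage$tpr),
                 mean(ev$perImage$fdr)))
  expect_equal(ev$summary$sd,
               c(stats::sd(ev$perImage$dice), stats::sd(ev$perImage$tpr),
                 stats::sd(ev$perImage$fdr)))
})

test_that("operating-point presets carry the validated thresholds", {
  mil <- operatingPoint("milwaukee")
  expect_equal(mil$T, 120)
  expect_equal(mil$chi, 0.75)
  oxf <- operatingPoint("oxford")
  expect_equal(oxf$T, 45)
  expect_equal(oxf$chi, 0.5)
})

test_that("threshold tuning returns the grid argmax with precision-favouring ties", {
  net <- fixtureModel()
  crops <- fixtureCrops()
  val <- lapply(crops[61:68], function(cr)
    list(image = cr$image, centres = cr$centres,
         coneWidthPx = cr$coneWidthPx))
  tGrid <- c(60, 120, 180)
  chiGrid <- c(0.5, 0.75)
  tuned <- tuneThresholds(net, val, tGrid, chiGrid)
  # exhaustive oracle over the same grid using the public pieces
  best <- NULL
  for (T in tGrid) for (chi in chiGrid) {
    dv <- vapply(val, function(case) {
      det <- detectCones(predictMap(net, case$image), T,
                         0.5 * case$coneWidthPx)
      computeMetrics(matchCones(coneCentres(det), case$centres,
                                case$coneWidthPx, chi,
                                c(96L, 96L)))@dice
    }, numeric(1))
    best <- rbind(best, data.frame(T = T, chi = chi, dice = mean(dv)))
  }
  best <- best[order(-best$dice, -best$T, best$chi), ][1, ]
  expect_equal(tuned$T, best$T)
  expect_equal(tuned$chi, best$chi)
  expect_equal(tuned$dice, best$dice, tolerance = 1e-12)
  # single-element grids return that element
  one <- tuneThresholds(net, val[1:2], tGrid = 120, chiGrid = 0.75)
  expect_equal(one$T, 120)
  expect_equal(one$chi, 0.75)
  expect_error(tuneThresholds(net, list(), tGrid, chiGrid), "empty")
})
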