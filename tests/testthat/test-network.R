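test_that("predictions preserve the input shape through the full U", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 1)
  img <- matrix(runif(96 * 96), 96, 96)
  pm <- predictMap(net, img)
  expect_identical(dim(mapValues(pm)), c(96L, 96L))
  expect_true(all(mapValues(pm) >= 0 & mapValues(pm) <= 255))
  expect_error(predictMap(net, matrix(0, 48, 48)), "96 x 96")
  expect_error(networkConfig(inputSize = 50L),
               "divisible")
})

test_that("prediction is deterministic in inference mode", {
  net <- fixtureModel()
  img <- fixtureCrops()[[5]]$image
  a <- predictMap(net, img)
  b <- predictMap(net, img)
  expect_identical(mapValues(a), mapValues(b))
})

test_that("the full-size architecture carries about 8.9 million parameters", {
  net <- buildNetwork(networkConfig(), seed = 1)
  expect_lt(abs(countParams(net) / 8.9e6 - 1), 0.10)
})

test_that("residual shortcuts account for exactly their projection weights", {
  cfg <- tinyNetworkConfig()
  with_res <- countParams(buildNetwork(cfg, seed = 1))
  cfg@useResidual <- FALSE
  without <- countParams(buildNetwork(cfg, seed = 1))
  # layer-by-layer: one (cin x f + f) 1x1 projection per module
  d <- cfg@depth
  filters <- cfg@baseFilters * 2L^(seq_len(d) - 1L)
  cins <- c(1L, filters[-d])                       # encoder inputs
  expected <- sum(cins * filters + filters) +      # encoder shortcuts
    filters[d] * cfg@bottleneckFilters + cfg@bottleneckFilters +
    sum(2L * filters * filters + filters)          # decoder shortcuts
  expect_equal(with_res - without, expected)
})

test_that("conv/pool/upsample kernels agree with direct oracles", {
  set.seed(3)
  x <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- coneUNet:::nnConvForward(x, w, b)
  ref <- array(0, c(6, 5, 3, 2))
  for (n in 1:2) for (co in 1:3) for (h in 1:6) for (w2 in 1:5) {
    s <- 0
    for (ki in 1:3) for (kj in 1:3) for (ci in 1:2) {
      hy <- h + ki - 2; wx <- w2 + kj - 2
      if (hy >= 1 && hy <= 6 && wx >= 1 && wx <= 5)
        s <- s + x[hy, wx, ci, n] * w[ki, kj, ci, co]
    }
    ref[h, w2, co, n] <- s + b[co]
  }
  expect_equal(y, ref, tolerance = 1e-5)

  p <- coneUNet:::nnMaxPool2(array(x[1:6, 1:4, , ], c(6, 4, 2, 2)))
  for (n in 1:2) for (c2 in 1:2) for (i in 1:3) for (j in 1:2)
    expect_equal(p$y[i, j, c2, n],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c2, n]))

  u <- coneUNet:::nnUpsample2(p$y)
  expect_equal(u[1, 1, 1, 1], p$y[1, 1, 1, 1])
  expect_equal(u[2, 2, 1, 1], p$y[1, 1, 1, 1])
  du <- coneUNet:::nnUpsample2Backward(u)
  expect_equal(du, 4 * p$y, tolerance = 1e-12)
})

test_that("conv backward matches finite differences (linear in weights)", {
  set.seed(4)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  b <- rnorm(2)
  dy <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  g <- coneUNet:::nnConvBackward(x, w, dy, TRUE)
  for (i in sample(length(w), 5)) {
    wp <- w; wp[i] <- wp[i] + 1e-2
    wm <- w; wm[i] <- wm[i] - 1e-2
    fd <- sum(dy * (coneUNet:::nnConvForward(x, wp, b) -
                    coneUNet:::nnConvForward(x, wm, b))) / 2e-2
    expect_equal(g$dw[i], fd, tolerance = 1e-3)
  }
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + 1e-2
    xm <- x; xm[i] <- xm[i] - 1e-2
    fd <- sum(dy * (coneUNet:::nnConvForward(xp, w, b) -
                    coneUNet:::nnConvForward(xm, w, b))) / 2e-2
    expect_equal(g$dx[i], fd, tolerance = 1e-3)
  }
})

test_that("module blocks backpropagate exact gradients", {
  set.seed(5)
  reg <- new.env(); reg$layers <- list()
  mod <- coneUNet:::newModuleBlock("m", 2L, 3L, c(1L, 2L), TRUE, reg)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  R <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  lossOf <- function() sum(mod$fwd(x, TRUE) * R)
  invisible(mod$fwd(x, TRUE))
  dx <- mod$bwd(R)
  for (lname in names(reg$layers)) {
    l <- reg$layers[[lname]]
    par <- if (l$type == "conv") "w" else "gamma"
    g <- if (l$type == "conv") l$dw else l$dgamma
    i <- sample(length(l[[par]]), 1)
    eps <- 1e-2
    orig <- l[[par]][i]
    l[[par]][i] <- orig + eps; lp <- lossOf()
    l[[par]][i] <- orig - eps; lm <- lossOf()
    l[[par]][i] <- orig
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 5e-3,
                 label = paste("gradient of", lname))
  }
  i <- 17; eps <- 1e-2
  xo <- x[i]
  x[i] <- xo + eps; lp <- lossOf()
  x[i] <- xo - eps; lm <- lossOf()
  x[i] <- xo
  expect_equal(dx[i], (lp - lm) / (2 * eps), tolerance = 5e-3)
})

test_that("training a tiny config on synthetic crops reduces the loss", {
  crops <- fixtureCrops()
  tr <- cropsToArrays(crops[1:48])
  va <- cropsToArrays(crops[49:60])
  net <- buildNetwork(tinyNetworkConfig(), seed = 2)
  trainNetwork(net, tr, va, trainingSchedule(maxEpochs = 2L, batchSize = 16L),
               seed = 4)
  h <- net@state$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_named(h, c("epoch", "loss", "val_loss", "lr"))
})

test_that("training is reproducible under a fixed seed", {
  crops <- fixtureCrops()
  tr <- cropsToArrays(crops[1:16])
  va <- cropsToArrays(crops[17:20])
  run <- function() {
    net <- buildNetwork(
      networkConfig(inputSize = 96L, depth = 1L, baseFilters = 4L,
                    bottleneckFilters = 8L, branchDepths = 1L), seed = 6)
    trainNetwork(net, tr, va,
                 trainingSchedule(maxEpochs = 1L, batchSize = 8L), seed = 9)
    net@state$history$loss
  }
  expect_identical(run(), run())
})

test_that("fine-tuning freezes everything outside the last expansive block", {
  crops <- fixtureCrops()
  tr <- cropsToArrays(crops[1:16])
  va <- cropsToArrays(crops[17:20])
  net <- buildNetwork(tinyNetworkConfig(), seed = 3)
  before <- getWeights(net)
  fineTune(net, tr, va, trainingSchedule(initialLR = 1e-4, maxEpochs = 1L,
                                         batchSize = 8L), seed = 2)
  after <- getWeights(net)
  frozenSame <- logical(); freeChanged <- logical()
  for (nm in names(before)) {
    free <- startsWith(nm, "dec1") || startsWith(nm, "out")
    if (grepl("(rmean|rvar)$", nm) && !free) {
      # frozen batch norms must not update their running statistics
      expect_identical(after[[nm]], before[[nm]], label = nm)
    } else if (!free) {
      expect_identical(after[[nm]], before[[nm]], label = nm)
    } else if (grepl("\\.(w|b|gamma|beta)$", nm)) {
      freeChanged <- c(freeChanged, !identical(after[[nm]], before[[nm]]))
    }
  }
  expect_true(any(freeChanged))
  expect_error(freezeForTransfer(net, "no_such_block"), "no layer")
})

test_that("frozen-parameter checksums are stable over repeated epochs", {
  crops <- fixtureCrops()
  tr <- cropsToArrays(crops[1:16])
  va <- cropsToArrays(crops[17:20])
  net <- buildNetwork(tinyNetworkConfig(), seed = 5)
  freezeForTransfer(net)
  frozenSum <- function() {
    w <- getWeights(net)
    sum(vapply(names(w)[!startsWith(names(w), "dec1") &
                        !startsWith(names(w), "out")],
               function(nm) sum(w[[nm]]), numeric(1)))
  }
  s0 <- frozenSum()
  trainNetwork(net, tr, va, trainingSchedule(initialLR = 1e-4,
                                             maxEpochs = 3L, batchSize = 8L),
               seed = 2)
  expect_identical(frozenSum(), s0)
})

test_that("fold assignment partitions groups disjointly and exhaustively", {
  groups <- sprintf("img%02d", 1:23)
  f <- assignFolds(groups, folds = 4L, seed = 3L)
  expect_setequal(names(f), groups)
  expect_setequal(unique(f), 1:4)
  expect_true(all(table(f) %in% c(5L, 6L)))
})

test_that("checkpoints round-trip weights exactly", {
  net <- fixtureModel()
  f <- tempfile(fileext = ".rds")
  saveModel(net, f)
  back <- loadModel(f)
  expect_identical(getWeights(back), getWeights(net))
  img <- fixtureCrops()[[3]]$image
  expect_identical(mapValues(predictMap(back, img)),
                   mapValues(predictMap(net, img)))
  unlink(f)
})

test_that("a non-finite loss aborts with a diagnostic", {
  crops <- fixtureCrops()
  tr <- cropsToArrays(crops[1:8])
  tr$y[1] <- NaN
  net <- buildNetwork(tinyNetworkConfig(), seed = 2)
  expect_error(
    trainNetwork(net, tr, tr, trainingSchedule(maxEpochs = 1L,
                                               batchSize = 8L)),
    "diverged")
})

test_that("batch augmentation transforms are exact dihedral elements", {
  a <- array(seq_len(8 * 8), c(8, 8, 1, 1))
  variants <- lapply(0:7, function(k) coneUNet:::dihedral4(a, k))
  expect_identical(variants[[1]], a)
  # all eight elements are distinct and preserve the multiset of values
  for (k in 2:8) {
    expect_false(identical(variants[[k]], a))
    expect_identical(sort(as.vector(variants[[k]])), sort(as.vector(a)))
  }
  expect_equal(length(unique(lapply(variants, as.vector))), 8L)
  # rotation by 90 four times is the identity
  r4 <- a
  for (i in 1:4) r4 <- coneUNet:::dihedral4(r4, 1L)
  expect_identical(r4, a)
})
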