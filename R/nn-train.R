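#' Construct a TrainingSchedule
#'
#' @param initialLR initial Adam learning rate
#' @param lrDecayFactor plateau decay factor
#' @param lrPatience epochs without qualifying improvement before decay
#' @param lrFloor minimum learning rate
#' @param improvementThreshold required validation-loss reduction (MSE units
#'   on \[0, 255\] labels) to count as an improvement
#' @param earlyStopPatience epochs without improvement before stopping
#' @param batchSize minibatch size
#' @param maxEpochs cap on epochs
#' @param folds cross-validation fold count
#' @return a [TrainingSchedule-class]
#' @export
trainingSchedule <- function(initialLR = 1e-3, lrDecayFactor = 0.5,
                             lrPatience = 5L, lrFloor = 1e-5,
                             improvementThreshold = 1.0,
                             earlyStopPatience = 7L, batchSize = 32L,
                             maxEpochs = 100L, folds = 4L) {
  new("TrainingSchedule", initialLR = initialLR,
      lrDecayFactor = lrDecayFactor, lrPatience = as.integer(lrPatience),
      lrFloor = lrFloor, improvementThreshold = improvementThreshold,
      earlyStopPatience = as.integer(earlyStopPatience),
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      folds = as.integer(folds))
}

#' @rdname trainingSchedule
#' @details `transferSchedule()` is the same schedule with the reduced
#'   initial learning rate (1e-4) used for transfer learning.
#' @export
transferSchedule <- function(initialLR = 1e-4, ...) {
  trainingSchedule(initialLR = initialLR, ...)
}

#' Initialise / advance the plateau learning-rate and early-stop state
#'
#' Pure replayable scheduler logic: a validation loss counts as an
#' improvement when it undercuts the best seen so far by at least the
#' improvement threshold. After `lrPatience` consecutive non-improving
#' epochs the learning rate is halved (never below `lrFloor`) and the decay
#' counter resets; after `earlyStopPatience` consecutive non-improving
#' epochs training stops.
#'
#' @param schedule a [TrainingSchedule-class]
#' @return `schedulerInit`: the initial state list.
#' @export
schedulerInit <- function(schedule) {
  list(lr = schedule@initialLR, best = Inf, waitLr = 0L, waitStop = 0L,
       halved = FALSE, stop = FALSE)
}

#' @rdname schedulerInit
#' @param state current scheduler state
#' @param valLoss the epoch's validation loss
#' @return `schedulerStep`: the updated state; fields `lr`, `halved` (was
#'   the learning rate reduced this epoch), and `stop` (early stop fired).
#' @examples
#' st <- schedulerInit(trainingSchedule())
#' for (loss in c(100, 99.9, 99.8, 99.7, 99.6, 99.5)) {
#'   st <- schedulerStep(st, loss, trainingSchedule())
#' }
#' st$lr  # halved at the 6th epoch
#' @export
schedulerStep <- function(state, valLoss, schedule) {
  state$halved <- FALSE
  if (state$best - valLoss >= schedule@improvementThreshold) {
    state$best <- valLoss
    state$waitLr <- 0L
    state$waitStop <- 0L
  } else {
    state$waitLr <- state$waitLr + 1L
    state$waitStop <- state$waitStop + 1L
    if (state$waitLr >= schedule@lrPatience) {
      newLr <- max(state$lr * schedule@lrDecayFactor, schedule@lrFloor)
      state$halved <- newLr < state$lr
      state$lr <- newLr
      state$waitLr <- 0L
    }
    if (state$waitStop >= schedule@earlyStopPatience) state$stop <- TRUE
  }
  state
}

#' Replay the scheduler against a scripted validation-loss sequence
#'
#' @param losses numeric vector of per-epoch validation losses
#' @param schedule a [TrainingSchedule-class]
#' @return data.frame with epoch, val_loss, lr (in force after the epoch),
#'   halved, stop
#' @export
replayScheduler <- function(losses, schedule = trainingSchedule()) {
  st <- schedulerInit(schedule)
  out <- vector("list", length(losses))
  for (i in seq_along(losses)) {
    st <- schedulerStep(st, losses[i], schedule)
    out[[i]] <- data.frame(epoch = i, val_loss = losses[i], lr = st$lr,
                           halved = st$halved, stop = st$stop)
    if (st$stop) {
      out <- out[seq_len(i)]
      break
    }
  }
  do.call(rbind, out)
}

# One Adam update over all trainable layers; state lives in the layer envs.
adamStep <- function(model, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in model@state$layers) {
    if (!l$trainable) next
    pars <- if (l$type == "conv") c("w", "b") else c("gamma", "beta")
    grds <- if (l$type == "conv") c("dw", "db") else c("dgamma", "dbeta")
    for (i in seq_along(pars)) {
      g <- l[[grds[i]]]
      if (is.null(g)) next
      mName <- paste0(".m_", pars[i])
      vName <- paste0(".v_", pars[i])
      if (is.null(l[[mName]])) {
        l[[mName]] <- g * 0
        l[[vName]] <- g * 0
      }
      l[[mName]] <- beta1 * l[[mName]] + (1 - beta1) * g
      l[[vName]] <- beta2 * l[[vName]] + (1 - beta2) * g^2
      mh <- l[[mName]] / (1 - beta1^t)
      vh <- l[[vName]] / (1 - beta2^t)
      l[[pars[i]]] <- l[[pars[i]]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  invisible(model)
}

datasetSize <- function(set) dim(set$x)[4L]

# Apply the k-th element of the dihedral group (k in 0..7: rotation by
# 90 * (k %% 4) degrees, then an x-axis flip when k >= 4) to an
# [H, W, C, N] array. Square inputs only; exact, no resampling.
dihedral4 <- function(a, k) {
  r <- k %% 4L
  if (r == 1L) a <- aperm(a, c(2L, 1L, 3L, 4L))[dim(a)[2L]:1L, , , , drop = FALSE]
  else if (r == 2L) a <- a[dim(a)[1L]:1L, dim(a)[2L]:1L, , , drop = FALSE]
  else if (r == 3L) a <- aperm(a, c(2L, 1L, 3L, 4L))[, dim(a)[1L]:1L, , , drop = FALSE]
  if (k >= 4L) a <- a[dim(a)[1L]:1L, , , , drop = FALSE]
  a
}

# The network regresses targets on an internal [0, 1] scale (labels / 255):
# Adam's step size is gradient-scale-free, so matching the parameter scale
# to the target scale is what makes desk-scale runs converge in few steps.
# All reported losses are MSE in [0, 255] label units (the two differ by
# the constant factor 255^2, so the minimiser is unchanged).
labelScale <- 255

# Mean squared error between prediction and target arrays, both on the
# internal [0, 1] scale, reported in [0, 255]^2 units.
mseLoss <- function(pred, target01) labelScale^2 * mean((pred - target01)^2)

evalLoss <- function(model, set, batchSize = 32L) {
  n <- datasetSize(set)
  tot <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    pred <- netForward(model, set$x[, , , i:j, drop = FALSE], training = FALSE)
    tot <- tot + sum((pred - set$y[, , , i:j, drop = FALSE] / labelScale)^2)
    i <- j + 1L
  }
  labelScale^2 * tot / (n * prod(dim(set$x)[1:3]))
}

#' Train the network by minibatch Adam on mean squared error
#'
#' Minimises MSE between predicted and ground-truth Gaussian label maps
#' (both on the \[0, 255\] scale). Per epoch the training set is reshuffled,
#' the validation loss is evaluated, and the plateau scheduler adjusts the
#' learning rate or triggers early stopping.
#'
#' @param model a [ConeUNet-class] (updated in place)
#' @param trainSet,valSet lists with `x` and `y` arrays of shape
#'   `[H, W, 1, N]`; see [cropsToArrays()]
#' @param schedule a [TrainingSchedule-class]
#' @param seed shuffling seed
#' @param augment apply a random dihedral transform (rotations by multiples
#'   of 90 degrees, x-axis flips) to each training batch, image and label
#'   alike; enlarges the effective training set eightfold at no resampling
#'   cost
#' @param verbose print per-epoch progress
#' @return the model, with a `history` data.frame (epoch, loss, val_loss,
#'   lr) stored in `model@state$history`
#' @export
trainNetwork <- function(model, trainSet, valSet,
                         schedule = trainingSchedule(), seed = 1L,
                         augment = FALSE, verbose = FALSE) {
  n <- datasetSize(trainSet)
  if (n < 1L || datasetSize(valSet) < 1L)
    stop("empty training or validation set", call. = FALSE)
  st <- schedulerInit(schedule)
  hist <- list()
  t <- model@state$adamT
  if (is.null(t)) t <- 0L
  withSeed(seed, {
    for (epoch in seq_len(schedule@maxEpochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      seen <- 0L
      i <- 1L
      while (i <= n) {
        idx <- ord[i:min(i + schedule@batchSize - 1L, n)]
        xb <- trainSet$x[, , , idx, drop = FALSE]
        yb <- trainSet$y[, , , idx, drop = FALSE] / labelScale
        if (augment) {
          k <- sample.int(8L, 1L) - 1L
          xb <- dihedral4(xb, k)
          yb <- dihedral4(yb, k)
        }
        pred <- netForward(model, xb, training = TRUE)
        loss <- mseLoss(pred, yb)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        dout <- 2 * (pred - yb) / length(pred)
        netBackward(model, dout)
        t <- t + 1L
        adamStep(model, st$lr, t)
        epochLoss <- epochLoss + loss * length(idx)
        seen <- seen + length(idx)
        i <- i + schedule@batchSize
      }
      valLoss <- evalLoss(model, valSet, schedule@batchSize)
      st <- schedulerStep(st, valLoss, schedule)
      hist[[epoch]] <- data.frame(epoch = epoch, loss = epochLoss / seen,
                                  val_loss = valLoss, lr = st$lr)
      if (verbose)
        message(sprintf("epoch %d: loss %.3f, val %.3f, lr %.2g",
                        epoch, epochLoss / seen, valLoss, st$lr))
      if (st$stop) break
    }
  })
  model@state$adamT <- t
  model@state$history <- do.call(rbind, hist)
  invisible(model)
}

#' Fine-tune a pre-trained network on a new dataset
#'
#' Transfer learning: freezes every block except the last expansive-path
#' module (and the output head) and continues training at the reduced
#' initial learning rate. Frozen parameters are bit-identical before and
#' after; frozen batch-norm layers keep their running statistics fixed.
#'
#' @param model a pre-trained [ConeUNet-class]
#' @param trainSet,valSet datasets as in [trainNetwork()]
#' @param schedule a [TrainingSchedule-class]; default [transferSchedule()]
#' @param unfreeze name prefixes of the blocks to train
#' @param seed shuffling seed
#' @return the model, invisibly
#' @export
fineTune <- function(model, trainSet, valSet, schedule = transferSchedule(),
                     unfreeze = c("dec1", "out"), seed = 1L) {
  freezeForTransfer(model, unfreeze)
  model@state$adamT <- 0L   # fresh optimiser state for the new stage
  for (l in model@state$layers) {
    for (nm in c(".m_w", ".v_w", ".m_b", ".v_b", ".m_gamma", ".v_gamma",
                 ".m_beta", ".v_beta")) l[[nm]] <- NULL
  }
  trainNetwork(model, trainSet, valSet, schedule, seed = seed)
}

#' Partition training groups into cross-validation folds
#'
#' Disjoint, exhaustive assignment of group labels to `folds` folds.
#'
#' @param groups vector of group identifiers (one per sample or per group)
#' @param folds number of folds
#' @param seed shuffle seed
#' @return named integer vector: fold of each unique group
#' @export
assignFolds <- function(groups, folds = 4L, seed = 1L) {
  u <- unique(groups)
  withSeed(seed, {
    perm <- sample(u)
    stats::setNames(rep(seq_len(folds), length.out = length(u))[match(u, perm)], u)
  })
}

#' Stack label-paired crops into training arrays
#'
#' Inputs are scaled per crop to \[0, 1\]; targets are the \[0, 255\] label
#' maps.
#'
#' @param crops list of lists with `image` and `label` ([LabelMap-class] or
#'   matrix) entries
#' @return list with `x` and `y` arrays of shape `[H, W, 1, N]`
#' @export
cropsToArrays <- function(crops) {
  n <- length(crops)
  H <- nrow(crops[[1L]]$image)
  W <- ncol(crops[[1L]]$image)
  x <- array(0, c(H, W, 1L, n))
  y <- array(0, c(H, W, 1L, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- normalizeInput(crops[[i]]$image)
    lab <- crops[[i]]$label
    y[, , 1L, i] <- if (is(lab, "LabelMap")) lab@values else lab
  }
  list(x = x, y = y)
}

#' Save / load a model checkpoint
#'
#' Weights, running statistics and configuration are serialised with
#' `saveRDS`.
#'
#' @param model a [ConeUNet-class]
#' @param path checkpoint path (.rds)
#' @return `saveModel`: the path invisibly; `loadModel`: the restored model
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, weights = getWeights(model)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  model <- buildNetwork(ck$config, seed = 1L)
  setWeights(model, ck$weights)
  model
}
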