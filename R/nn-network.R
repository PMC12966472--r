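#' Construct a NetworkConfig
#'
#' The full-size defaults (depth 4, filters 16-32-64-128 with a
#' 392-filter bottleneck, parallel branches of stacked 3x3 convolutions
#' with effective kernels 3x3/5x5/7x7) give approximately 8.9 million
#' trainable parameters. `tinyNetworkConfig()` is a first-class desk-scale
#' variant for CPU training and tests.
#'
#' @param inputSize square input side, pixels; must divide by 2^depth
#' @param depth number of encoder levels (2x2 stride-2 max-poolings)
#' @param baseFilters filters at the first level, doubling per level
#' @param bottleneckFilters filters at the bottom of the U
#' @param branchDepths stacked-3x3 counts of the parallel branches
#'   (`c(1, 2, 3)` means effective kernel sizes 3, 5 and 7)
#' @param useResidual include residual shortcut projections
#' @return a [NetworkConfig-class]
#' @export
networkConfig <- function(inputSize = 96L, depth = 4L, baseFilters = 16L,
                          bottleneckFilters = 392L,
                          branchDepths = c(1L, 2L, 3L),
                          useResidual = TRUE) {
  new("NetworkConfig", inputSize = as.integer(inputSize),
      depth = as.integer(depth), baseFilters = as.integer(baseFilters),
      bottleneckFilters = as.integer(bottleneckFilters),
      branchDepths = as.integer(branchDepths), useResidual = useResidual)
}

#' @rdname networkConfig
#' @export
tinyNetworkConfig <- function(inputSize = 96L) {
  networkConfig(inputSize = inputSize, depth = 2L, baseFilters = 8L,
                bottleneckFilters = 32L, branchDepths = c(1L, 2L))
}

#' Build the multi-scale encoder-decoder network
#'
#' Symmetric encoder-decoder: each level applies one multi-scale module
#' (parallel stacked-3x3 branches, concatenation, 1x1 fusion, 1x1-projected
#' residual shortcut, batch norm before ReLU) followed by 2x2 max pooling on
#' the contracting path; the expansive path upsamples, concatenates the
#' matching encoder features and applies the mirrored module; a final 1x1
#' convolution regresses the single-channel probability map. All
#' convolutions zero-pad, so every feature map keeps its level's spatial
#' size and the prediction matches the input shape. Weights are initialised
#' with random orthogonal matrices.
#'
#' @param config a [NetworkConfig-class]
#' @param seed initialisation seed
#' @return a [ConeUNet-class]
#' @examples
#' net <- buildNetwork(tinyNetworkConfig(), seed = 1)
#' countParams(net)
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
  validObject(config)
  d <- config@depth
  filters <- config@baseFilters * 2L^(seq_len(d) - 1L)
  st <- new.env(parent = emptyenv())
  st$layers <- list()
  withSeed(seed, {
    st$encoders <- lapply(seq_len(d), function(l) {
      cin <- if (l == 1L) 1L else filters[l - 1L]
      newModuleBlock(paste0("enc", l), cin, filters[l], config@branchDepths,
                     config@useResidual, st, needDx = l > 1L)
    })
    st$bottleneck <- newModuleBlock("bottleneck", filters[d],
                                    config@bottleneckFilters,
                                    config@branchDepths, config@useResidual, st)
    # channel-reducing 1x1 up-convolutions after each upsampling
    st$upReduce <- lapply(seq_len(d), function(l) {
      lowC <- if (l == d) config@bottleneckFilters else filters[l + 1L]
      newConvLayer(paste0("dec", l, ".up"), 1L, lowC, filters[l], st)
    })
    st$decoders <- lapply(seq_len(d), function(l) {
      newModuleBlock(paste0("dec", l), 2L * filters[l], filters[l],
                     config@branchDepths, config@useResidual, st)
    })
    st$out <- newConvLayer("out", 1L, filters[1L], 1L, st)
  })
  st$filters <- filters
  new("ConeUNet", config = config, state = st)
}

# Forward pass on a [H, W, 1, N] array; returns [H, W, 1, N] predictions.
# Caches needed for backward are stored in the layer environments.
netForward <- function(model, x, training = FALSE) {
  st <- model@state
  d <- model@config@depth
  st$skip <- vector("list", d)
  st$poolArg <- vector("list", d)
  st$poolDim <- vector("list", d)
  cur <- x
  for (l in seq_len(d)) {
    cur <- st$encoders[[l]]$fwd(cur, training)
    st$skip[[l]] <- cur
    st$poolDim[[l]] <- dim(cur)
    p <- nnMaxPool2(cur)
    st$poolArg[[l]] <- p$argmax
    cur <- p$y
  }
  cur <- st$bottleneck$fwd(cur, training)
  for (l in rev(seq_len(d))) {
    up <- st$upReduce[[l]]$fwd(nnUpsample2(cur), training)
    cur <- st$decoders[[l]]$fwd(concatChannels(up, st$skip[[l]]), training)
  }
  st$out$fwd(cur, training)
}

netBackward <- function(model, dout) {
  st <- model@state
  d <- model@config@depth
  skipGrad <- vector("list", d)
  dcur <- st$out$bwd(dout)
  for (l in seq_len(d)) {
    dmod <- st$decoders[[l]]$bwd(dcur)
    upC <- dim(dmod)[3L] %/% 2L
    dup <- dmod[, , seq_len(upC), , drop = FALSE]
    skipGrad[[l]] <- dmod[, , upC + seq_len(upC), , drop = FALSE]
    dcur <- nnUpsample2Backward(st$upReduce[[l]]$bwd(dup))
  }
  dcur <- st$bottleneck$bwd(dcur)
  for (l in rev(seq_len(d))) {
    dpool <- nnMaxPool2Backward(dcur, st$poolArg[[l]], st$poolDim[[l]])
    dcur <- st$encoders[[l]]$bwd(dpool + skipGrad[[l]])
  }
  st$skip <- NULL
  dcur
}

#' Count trainable parameters of a network
#'
#' @param model a [ConeUNet-class]
#' @param trainableOnly count only currently unfrozen layers
#' @return integer parameter count
#' @export
countParams <- function(model, trainableOnly = FALSE) {
  sum(vapply(model@state$layers, function(l) {
    if (trainableOnly && !l$trainable) return(0)
    if (l$type == "conv") length(l$w) + length(l$b)
    else length(l$gamma) + length(l$beta)
  }, numeric(1)))
}

#' Extract a named list of all parameter arrays
#'
#' Useful for freeze-contract checks and checkpointing.
#'
#' @param model a [ConeUNet-class]
#' @return named list of numeric arrays
#' @export
getWeights <- function(model) {
  out <- list()
  for (l in model@state$layers) {
    if (l$type == "conv") {
      out[[paste0(l$name, ".w")]] <- l$w
      out[[paste0(l$name, ".b")]] <- l$b
    } else {
      out[[paste0(l$name, ".gamma")]] <- l$gamma
      out[[paste0(l$name, ".beta")]] <- l$beta
      out[[paste0(l$name, ".rmean")]] <- l$rmean
      out[[paste0(l$name, ".rvar")]] <- l$rvar
    }
  }
  out
}

#' Restore parameters extracted with [getWeights()]
#'
#' @param model a [ConeUNet-class]
#' @param weights named list from [getWeights()]
#' @return the model, invisibly
#' @export
setWeights <- function(model, weights) {
  for (l in model@state$layers) {
    if (l$type == "conv") {
      l$w <- weights[[paste0(l$name, ".w")]]
      l$b <- weights[[paste0(l$name, ".b")]]
    } else {
      l$gamma <- weights[[paste0(l$name, ".gamma")]]
      l$beta <- weights[[paste0(l$name, ".beta")]]
      l$rmean <- weights[[paste0(l$name, ".rmean")]]
      l$rvar <- weights[[paste0(l$name, ".rvar")]]
    }
  }
  invisible(model)
}

#' Freeze all but the last expansive block for transfer learning
#'
#' Marks every layer outside the designated blocks as non-trainable: their
#' parameters receive no updates and frozen batch-norm layers keep using
#' (and stop updating) their running statistics. By default the last
#' expansive-path module (`dec1`) and the output head stay trainable.
#'
#' @param model a [ConeUNet-class]
#' @param unfreeze name prefixes of blocks to keep trainable
#' @return the model, invisibly
#' @export
freezeForTransfer <- function(model, unfreeze = c("dec1", "out")) {
  hits <- 0L
  for (l in model@state$layers) {
    free <- any(vapply(unfreeze, function(u)
      l$name == u || startsWith(l$name, paste0(u, ".")), logical(1)))
    l$trainable <- free
    hits <- hits + free
  }
  if (hits == 0L) stop("no layer matches the unfreeze prefixes", call. = FALSE)
  invisible(model)
}

# Scale a raw image crop to the network's input range [0, 1].
normalizeInput <- function(img) {
  m <- max(img)
  if (m > 0) img / m else img
}

#' Predict a cone probability map for one input crop
#'
#' Runs the network in inference mode (batch norm uses running statistics)
#' and clips the regression output to \[0, 255\] for downstream thresholding.
#'
#' @param model a trained [ConeUNet-class]
#' @param image numeric matrix matching the configured input size
#' @param imageId identifier stored on the result
#' @return a [ProbabilityMap-class]
#' @export
predictMap <- function(model, image, imageId = "image") {
  s <- model@config@inputSize
  if (!all(dim(image) == c(s, s)))
    stop(sprintf("input must be %d x %d", s, s), call. = FALSE)
  x <- array(normalizeInput(image), c(s, s, 1L, 1L))
  y <- netForward(model, x, training = FALSE)
  new("ProbabilityMap", values = clip01(255 * matrix(y, s, s), 0, 255),
      sourceImageId = imageId)
}
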