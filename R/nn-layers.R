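# Layer objects for the encoder-decoder network. Each layer is an
# environment holding its parameters, gradients and forward/backward caches;
# composite modules orchestrate sub-layers. Parameters update in place
# during training, so the network object has reference semantics.

# Orthogonal initialisation: reshape the kernel to (fan_in x Cout) and take
# the Q factor of a Gaussian matrix.
orthogonalInit <- function(dims) {
  fanIn <- prod(dims[-length(dims)])
  cout <- dims[length(dims)]
  big <- max(fanIn, cout)
  A <- matrix(stats::rnorm(big * min(fanIn, cout)), big)
  Q <- qr.Q(qr(A))
  W <- if (fanIn >= cout) Q[seq_len(fanIn), seq_len(cout), drop = FALSE]
       else t(Q[seq_len(cout), seq_len(fanIn), drop = FALSE])
  array(W, dim = dims)
}

newConvLayer <- function(name, kh, cin, cout, registry, needDx = TRUE) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$type <- "conv"
  e$trainable <- TRUE
  e$w <- orthogonalInit(c(kh, kh, cin, cout))
  e$b <- numeric(cout)
  e$fwd <- function(x, training) {
    e$x <- x
    nnConvForward(x, e$w, e$b)
  }
  e$bwd <- function(dy) {
    g <- nnConvBackward(e$x, e$w, dy, needDx)
    e$dw <- g$dw
    e$db <- g$db
    e$x <- NULL
    g$dx
  }
  registry$layers[[name]] <- e
  e
}

# Batch norm, optionally with a fused ReLU (activations always follow a
# batch norm here, and the fusion avoids two full-size allocations).
newBnLayer <- function(name, c, registry, relu = FALSE, momentum = 0.99,
                       eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$type <- "bn"
  e$trainable <- TRUE
  e$relu <- relu
  e$gamma <- rep(1, c)
  e$beta <- numeric(c)
  e$rmean <- numeric(c)
  e$rvar <- rep(1, c)
  e$fwd <- function(x, training) {
    # frozen batch-norm uses running statistics even while training
    useBatch <- training && e$trainable
    r <- nnBnForward(x, e$gamma, e$beta, e$rmean, e$rvar, momentum,
                     useBatch, eps, e$relu)
    if (useBatch) {
      e$rmean <- r$rmean
      e$rvar <- r$rvar
    }
    e$x <- x
    e$mean <- r$mean
    e$invstd <- r$invstd
    e$batchMode <- useBatch
    if (e$relu) e$y <- r$y   # binding only; the ReLU mask is y > 0
    r$y
  }
  e$bwd <- function(dy) {
    g <- nnBnBackward(e$x, dy, e$gamma, e$mean, e$invstd, e$batchMode,
                      if (e$relu) e$y else NULL)
    e$dgamma <- g$dgamma
    e$dbeta <- g$dbeta
    e$x <- NULL
    e$y <- NULL
    g$dx
  }
  registry$layers[[name]] <- e
  e
}

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# One multi-scale module. The parallel branches' first 3x3 convolutions all
# see the module input, so they are computed as a single entry convolution
# with nb*f output channels (one GEMM, one im2col) whose channel slices
# seed the branches; branch k then stacks branchDepths[k] - 1 further 3x3
# convolutions (bn + ReLU between convs). Branch outputs are concatenated,
# fused by a 1x1 convolution, a 1x1-projected residual shortcut is added,
# and batch norm + ReLU close the module.
newModuleBlock <- function(name, cin, f, branchDepths, useResidual, registry,
                           needDx = TRUE) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  nb <- length(branchDepths)
  e$nb <- nb
  e$entry <- newConvLayer(paste0(name, ".entry"), 3L, cin, nb * f, registry,
                          needDx = needDx)
  e$tails <- lapply(seq_len(nb), function(k) {
    layers <- list()
    for (j in seq_len(branchDepths[k] - 1L)) {
      layers <- c(layers, list(
        newBnLayer(sprintf("%s.b%dc%d.bn", name, k, j), f, registry,
                   relu = TRUE),
        newConvLayer(sprintf("%s.b%dc%d", name, k, j + 1L), 3L, f, f,
                     registry)))
    }
    layers
  })
  e$fuse <- newConvLayer(paste0(name, ".fuse"), 1L, nb * f, f, registry)
  e$useResidual <- useResidual
  if (useResidual)
    e$shortcut <- newConvLayer(paste0(name, ".shortcut"), 1L, cin, f,
                               registry, needDx = needDx)
  e$bn <- newBnLayer(paste0(name, ".bn"), f, registry, relu = TRUE)
  e$f <- f

  e$fwd <- function(x, training) {
    ent <- e$entry$fwd(x, training)
    cat <- ent
    for (k in seq_len(nb)) {
      if (!length(e$tails[[k]])) next
      cur <- ent[, , (k - 1L) * f + seq_len(f), , drop = FALSE]
      for (l in e$tails[[k]]) cur <- l$fwd(cur, training)
      cat[, , (k - 1L) * f + seq_len(f), ] <- cur
    }
    y <- e$fuse$fwd(cat, training)
    if (e$useResidual) y <- y + e$shortcut$fwd(x, training)
    e$bn$fwd(y, training)
  }
  e$bwd <- function(dy) {
    d <- e$bn$bwd(dy)
    dxShort <- if (e$useResidual) e$shortcut$bwd(d) else NULL
    dent <- e$fuse$bwd(d)
    for (k in seq_len(nb)) {
      if (!length(e$tails[[k]])) next
      dk <- dent[, , (k - 1L) * f + seq_len(f), , drop = FALSE]
      for (l in rev(e$tails[[k]])) dk <- l$bwd(dk)
      dent[, , (k - 1L) * f + seq_len(f), ] <- dk
    }
    dEntry <- e$entry$bwd(dent)
    if (is.null(dEntry)) return(NULL)   # input layer: no dx needed
    if (is.null(dxShort)) dEntry else dEntry + dxShort
  }
  e
}
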