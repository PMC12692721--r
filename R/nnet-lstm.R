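## Bidirectional LSTM sequence-labelling head.
##
## A compact, self-contained implementation: stacked bidirectional LSTM
## layers over variable-length per-residue feature sequences, an optional
## linear bridge into a three-layer ReLU feed-forward classification head,
## masked softmax cross-entropy (the ninth, mask class never contributes
## to the loss or the gradient), exact backpropagation through time, and
## Adam with decoupled-style L2 weight decay. Sequences are processed at
## their native length (no padding), so batched and unbatched forward
## passes are exactly equivalent.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Network configuration
#'
#' Defaults mirror the reference training setup: two bidirectional LSTM
#' layers of 512 units per direction, a 2048 -> 1024 -> 512 -> 9 ReLU
#' head (a linear bridge maps the 2 x hidden LSTM output to the head
#' input when the dimensions differ), dropout starting at 0.7 and
#' annealed by 0.1 per validation plateau down to 0, Adam with learning
#' rate 1e-4 and weight decay 1e-4, stepwise learning-rate decay to the
#' 1e-5 floor once dropout reaches 0, and early stopping with patience
#' 13. Desk-scale tests use much smaller widths.
#'
#' @param inputDim per-residue feature dimension.
#' @param lstmLayers number of bidirectional LSTM layers.
#' @param hidden hidden units per direction.
#' @param headDims feed-forward head layer sizes (input, hidden...,
#'   output); the output must be 9 (eight structural classes + mask).
#' @param dropoutStart,dropoutEnd dropout annealing range.
#' @param dropoutStep dropout reduction per plateau event.
#' @param dropoutPatience epochs without validation improvement that
#'   define a plateau.
#' @param lr,weightDecay Adam settings.
#' @param lrFloor,lrDecay learning-rate floor and per-plateau decay factor
#'   (applied only after dropout reaches its end value).
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping.
#' @param batchSize chains per gradient step.
#' @return list of class `NetConfig`.
#' @export
netConfig <- function(inputDim, lstmLayers = 2L, hidden = 512L,
                      headDims = c(2048L, 1024L, 512L, 9L),
                      dropoutStart = 0.7, dropoutEnd = 0,
                      dropoutStep = 0.1, dropoutPatience = 5L,
                      lr = 1e-4, weightDecay = 1e-4,
                      lrFloor = 1e-5, lrDecay = 0.5,
                      earlyStopPatience = 13L, batchSize = 4L) {
  if (utils::tail(headDims, 1) != 9L)
    stop("config error: output layer must have 9 classes (8 + mask)")
  if (lstmLayers < 1 || hidden < 1 || inputDim < 1)
    stop("config error: invalid dimensions")
  structure(list(inputDim = as.integer(inputDim),
                 lstmLayers = as.integer(lstmLayers),
                 hidden = as.integer(hidden),
                 headDims = as.integer(headDims),
                 dropoutStart = dropoutStart, dropoutEnd = dropoutEnd,
                 dropoutStep = dropoutStep,
                 dropoutPatience = as.integer(dropoutPatience),
                 lr = lr, weightDecay = weightDecay, lrFloor = lrFloor,
                 lrDecay = lrDecay,
                 earlyStopPatience = as.integer(earlyStopPatience),
                 batchSize = as.integer(batchSize)),
            class = "NetConfig")
}

initMatrix <- function(nr, nc) {
  r <- 1 / sqrt(max(nc, 1))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Build a model from a configuration
#'
#' Initializes all parameters (uniform in +/- 1/sqrt(fan-in); LSTM forget
#' gate biases at +1) under the given seed.
#'
#' @param config from [netConfig()].
#' @param seed RNG seed for initialization.
#' @return model handle (list with `config` and `params`).
#' @export
buildModel <- function(config, seed = 1L) {
  set.seed(seed)
  h <- config$hidden
  lstm <- vector("list", config$lstmLayers)
  inDim <- config$inputDim
  for (l in seq_len(config$lstmLayers)) {
    mk <- function() {
      b <- numeric(4 * h)
      b[(h + 1):(2 * h)] <- 1          # forget-gate bias
      list(W = initMatrix(4 * h, inDim), U = initMatrix(4 * h, h), b = b)
    }
    lstm[[l]] <- list(fwd = mk(), bwd = mk())
    inDim <- 2 * h
  }
  bridge <- list()    # empty when 2*hidden already matches the head input
  if (2 * h != config$headDims[1])
    bridge <- list(W = initMatrix(config$headDims[1], 2 * h),
                   b = numeric(config$headDims[1]))
  head <- vector("list", length(config$headDims) - 1)
  for (i in seq_along(head))
    head[[i]] <- list(W = initMatrix(config$headDims[i + 1],
                                     config$headDims[i]),
                      b = numeric(config$headDims[i + 1]))
  structure(list(config = config,
                 params = list(lstm = lstm, bridge = bridge, head = head)),
            class = "BiLstmModel")
}

#' @export
print.BiLstmModel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "BiLstmModel: %d-layer Bi-LSTM (%d/direction), head %s, input %d\n",
    cfg$lstmLayers, cfg$hidden, paste(cfg$headDims, collapse = "->"),
    cfg$inputDim))
  invisible(x)
}

## single-direction LSTM forward; returns hidden states and caches
lstmDirForward <- function(p, X) {
  Tn <- nrow(X); h <- ncol(p$U)
  I <- F <- G <- O <- C <- HC <- H <- matrix(0, Tn, h)
  hprev <- numeric(h); cprev <- numeric(h)
  for (t in seq_len(Tn)) {
    z <- as.numeric(p$W %*% X[t, ] + p$U %*% hprev + p$b)
    i <- sigmoid(z[1:h]); f <- sigmoid(z[(h + 1):(2 * h)])
    g <- tanh(z[(2 * h + 1):(3 * h)]); o <- sigmoid(z[(3 * h + 1):(4 * h)])
    cc <- f * cprev + i * g
    hc <- tanh(cc)
    I[t, ] <- i; F[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- cc; HC[t, ] <- hc
    H[t, ] <- o * hc
    hprev <- H[t, ]; cprev <- cc
  }
  list(H = H, I = I, F = F, G = G, O = O, C = C, HC = HC, X = X)
}

## single-direction LSTM backward; dH is T x h gradient on the outputs
lstmDirBackward <- function(p, cache, dH) {
  Tn <- nrow(dH); h <- ncol(dH)
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, nrow(p$U), ncol(p$U))
  db <- numeric(4 * h)
  dX <- matrix(0, Tn, ncol(p$W))
  dhnext <- numeric(h); dcnext <- numeric(h)
  for (t in Tn:1) {
    dh <- dH[t, ] + dhnext
    hc <- cache$HC[t, ]; o <- cache$O[t, ]
    i <- cache$I[t, ]; f <- cache$F[t, ]; g <- cache$G[t, ]
    cprev <- if (t > 1) cache$C[t - 1, ] else numeric(h)
    hprev <- if (t > 1) cache$H[t - 1, ] else numeric(h)
    do <- dh * hc
    dc <- dcnext + dh * o * (1 - hc * hc)
    di <- dc * g; df <- dc * cprev; dg <- dc * i
    dcnext <- dc * f
    dz <- c(di * i * (1 - i), df * f * (1 - f),
            dg * (1 - g * g), do * o * (1 - o))
    dW <- dW + tcrossprod(dz, cache$X[t, ])
    dU <- dU + tcrossprod(dz, hprev)
    db <- db + dz
    dX[t, ] <- as.numeric(crossprod(p$W, dz))
    dhnext <- as.numeric(crossprod(p$U, dz))
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

## full forward for one sequence; dropout masks drawn when dropout > 0
nnForwardSeq <- function(model, X, dropout = 0, training = FALSE) {
  p <- model$params
  caches <- list()
  A <- X
  for (l in seq_along(p$lstm)) {
    fc <- lstmDirForward(p$lstm[[l]]$fwd, A)
    Arev <- A[rev(seq_len(nrow(A))), , drop = FALSE]
    bc <- lstmDirForward(p$lstm[[l]]$bwd, Arev)
    Hb <- bc$H[rev(seq_len(nrow(A))), , drop = FALSE]
    out <- cbind(fc$H, Hb)
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(out), 1, 1 - dropout) /
                       (1 - dropout), nrow(out), ncol(out))
      out <- out * mask
    }
    caches[[l]] <- list(fwd = fc, bwd = bc, dropMask = mask, input = A)
    A <- out
  }
  bridgeCache <- NULL
  if (length(p$bridge)) {
    Z <- A %*% t(p$bridge$W)
    Z <- sweep(Z, 2, p$bridge$b, "+")
    bridgeCache <- list(input = A)
    A <- Z
  }
  headCache <- list()
  nh <- length(p$head)
  for (i in seq_len(nh)) {
    Z <- A %*% t(p$head[[i]]$W)
    Z <- sweep(Z, 2, p$head[[i]]$b, "+")
    act <- if (i < nh) pmax(Z, 0) else Z
    headCache[[i]] <- list(input = A, Z = Z)
    A <- act
  }
  list(logits = A, lstm = caches, bridge = bridgeCache, head = headCache)
}

## masked softmax cross-entropy; y uses 0 (or 9) for masked positions
maskedSoftmaxLoss <- function(logits, y, nUnmasked) {
  keep <- which(y >= 1 & y <= 8)
  dL <- matrix(0, nrow(logits), ncol(logits))
  loss <- 0
  for (t in keep) {
    z <- logits[t, ] - max(logits[t, ])
    p <- exp(z) / sum(exp(z))
    loss <- loss - log(max(p[y[t]], 1e-300))
    grad <- p
    grad[y[t]] <- grad[y[t]] - 1
    dL[t, ] <- grad / nUnmasked
  }
  list(loss = loss, dLogits = dL, n = length(keep))
}

zeroLike <- function(params) rapply(params, function(x) x * 0, how = "replace")

## loss and gradients over a batch of sequences
nnLossGrad <- function(model, batch, dropout = 0, training = FALSE) {
  p <- model$params
  grads <- zeroLike(p)
  nUnmasked <- sum(vapply(batch, function(s) sum(s$y >= 1 & s$y <= 8), 0))
  if (nUnmasked == 0)
    return(list(loss = 0, grads = grads, n = 0))
  totalLoss <- 0
  for (s in batch) {
    fwd <- nnForwardSeq(model, s$X, dropout = dropout, training = training)
    ml <- maskedSoftmaxLoss(fwd$logits, s$y, nUnmasked)
    totalLoss <- totalLoss + ml$loss
    dA <- ml$dLogits
    nh <- length(p$head)
    for (i in nh:1) {
      hc <- fwd$head[[i]]
      if (i < nh) dA <- dA * (hc$Z > 0)
      grads$head[[i]]$W <- grads$head[[i]]$W + crossprod(dA, hc$input)
      grads$head[[i]]$b <- grads$head[[i]]$b + colSums(dA)
      dA <- dA %*% p$head[[i]]$W
    }
    if (length(p$bridge)) {
      grads$bridge$W <- grads$bridge$W + crossprod(dA, fwd$bridge$input)
      grads$bridge$b <- grads$bridge$b + colSums(dA)
      dA <- dA %*% p$bridge$W
    }
    for (l in length(p$lstm):1) {
      lc <- fwd$lstm[[l]]
      if (!is.null(lc$dropMask)) dA <- dA * lc$dropMask
      h <- ncol(lc$fwd$H)
      dHf <- dA[, seq_len(h), drop = FALSE]
      dHb <- dA[, h + seq_len(h), drop = FALSE]
      gf <- lstmDirBackward(p$lstm[[l]]$fwd, lc$fwd, dHf)
      rev_idx <- rev(seq_len(nrow(dA)))
      gb <- lstmDirBackward(p$lstm[[l]]$bwd, lc$bwd,
                            dHb[rev_idx, , drop = FALSE])
      grads$lstm[[l]]$fwd$W <- grads$lstm[[l]]$fwd$W + gf$dW
      grads$lstm[[l]]$fwd$U <- grads$lstm[[l]]$fwd$U + gf$dU
      grads$lstm[[l]]$fwd$b <- grads$lstm[[l]]$fwd$b + gf$db
      grads$lstm[[l]]$bwd$W <- grads$lstm[[l]]$bwd$W + gb$dW
      grads$lstm[[l]]$bwd$U <- grads$lstm[[l]]$bwd$U + gb$dU
      grads$lstm[[l]]$bwd$b <- grads$lstm[[l]]$bwd$b + gb$db
      dA <- gf$dX + gb$dX[rev_idx, , drop = FALSE]
    }
  }
  list(loss = totalLoss / nUnmasked, grads = grads, n = nUnmasked)
}

## flat parameter access (used by optimizer and gradient checks)
flattenParams <- function(params) unlist(params, use.names = FALSE)

unflattenParams <- function(params, flat) {
  pos <- 0L
  rapply(params, function(x) {
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
  }, how = "replace")
}

#' Predict per-residue labels
#'
#' Argmax of the logits over the eight structural classes only (the mask
#' class is never predicted); deterministic tie-break toward the lowest
#' class index, i.e. H for an all-equal row.
#'
#' @param model a trained model handle.
#' @param X per-residue feature matrix (one chain), columns matching the
#'   model's input dimension.
#' @param scores also return the logits.
#' @return character labels (and a `T x 9` score matrix when requested).
#' @export
predictLabels <- function(model, X, scores = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model$config$inputDim)
    stop("feature dimension mismatch: ", ncol(X), " vs ",
         model$config$inputDim)
  logits <- nnForwardSeq(model, X)$logits
  lab <- LABELS8[max.col(logits[, 1:8, drop = FALSE], ties.method = "first")]
  if (scores) list(labels = lab, scores = logits) else lab
}

#' Training loss of a batch (no parameter update)
#'
#' @param model model handle.
#' @param batch list of sequences, each `list(X, y)` where `y` is an
#'   integer vector (1..8, with 0 or 9 marking masked positions).
#' @return mean masked cross-entropy.
#' @export
modelLoss <- function(model, batch) nnLossGrad(model, batch)$loss

batchAccuracy <- function(model, batch) {
  correct <- 0; total <- 0
  for (s in batch) {
    keep <- s$y >= 1 & s$y <= 8
    if (!any(keep)) next
    pred <- predictLabels(model, s$X)
    correct <- correct + sum(pred[keep] == LABELS8[s$y[keep]])
    total <- total + sum(keep)
  }
  if (total == 0) NA_real_ else correct / total
}

#' Train the sequence-labelling model
#'
#' Masked cross-entropy over the eight structural classes; positions with
#' the mask target are excluded from loss, gradient and metrics. Dropout
#' is annealed from its start value in steps of `dropoutStep` whenever the
#' validation accuracy plateaus (no improvement of at least 1e-4 for
#' `dropoutPatience` epochs); once dropout reaches its end value, further
#' plateau events decay the learning rate by `lrDecay` down to `lrFloor`.
#' Early stopping after `earlyStopPatience` epochs without validation
#' improvement; the best checkpoint (by validation accuracy) is retained.
#' All randomness (shuffling, dropout) derives from `seed`.
#'
#' @param model from [buildModel()].
#' @param train list of sequences `list(X, y)`.
#' @param val validation sequences; defaults to the training set.
#' @param epochs maximum epochs.
#' @param seed RNG seed.
#' @param targetAccuracy optional early exit once the validation accuracy
#'   reaches this value.
#' @param verbose print per-epoch lines.
#' @return the model with trained parameters and a `log` data.frame
#'   (epoch, loss, train/validation accuracy, dropout, lr).
#' @export
trainModel <- function(model, train, val = NULL, epochs = 50L, seed = 1L,
                       targetAccuracy = NULL, verbose = FALSE) {
  if (!length(train)) stop("empty training set")
  if (is.null(val)) val <- train
  cfg <- model$config
  set.seed(seed)
  params <- model$params
  mState <- zeroLike(params)
  vState <- zeroLike(params)
  adamT <- 0
  lr <- cfg$lr
  dropout <- cfg$dropoutStart
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  bestAcc <- -Inf; bestParams <- params
  sinceBest <- 0; sincePlateau <- 0
  log <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train))
    epLoss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = cfg$batchSize)) {
      idx <- ord[start:min(start + cfg$batchSize - 1, length(ord))]
      model$params <- params
      lg <- nnLossGrad(model, train[idx], dropout = dropout, training = TRUE)
      if (lg$n == 0) next
      epLoss <- epLoss + lg$loss; nb <- nb + 1
      gFlat <- flattenParams(lg$grads) +
        cfg$weightDecay * flattenParams(params)
      adamT <- adamT + 1
      mFlat <- beta1 * flattenParams(mState) + (1 - beta1) * gFlat
      vFlat <- beta2 * flattenParams(vState) + (1 - beta2) * gFlat^2
      mHat <- mFlat / (1 - beta1^adamT)
      vHat <- vFlat / (1 - beta2^adamT)
      pFlat <- flattenParams(params) - lr * mHat / (sqrt(vHat) + eps)
      params <- unflattenParams(params, pFlat)
      mState <- unflattenParams(mState, mFlat)
      vState <- unflattenParams(vState, vFlat)
    }
    model$params <- params
    trainAcc <- batchAccuracy(model, train)
    valAcc <- batchAccuracy(model, val)
    log <- rbind(log, data.frame(epoch = ep, loss = epLoss / max(nb, 1),
                                 train_accuracy = trainAcc,
                                 val_accuracy = valAcc,
                                 dropout = dropout, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d loss %.4f train %.4f val %.4f do %.1f lr %.2g",
                      ep, epLoss / max(nb, 1), trainAcc, valAcc, dropout, lr))
    improved <- is.finite(valAcc) && valAcc > bestAcc + 1e-4
    if (is.finite(valAcc) && valAcc > bestAcc) {
      bestAcc <- valAcc
      bestParams <- params
    }
    if (improved) {
      sinceBest <- 0; sincePlateau <- 0
    } else {
      sinceBest <- sinceBest + 1
      sincePlateau <- sincePlateau + 1
    }
    if (!is.null(targetAccuracy) && is.finite(valAcc) &&
        valAcc >= targetAccuracy) break
    if (sincePlateau >= cfg$dropoutPatience) {
      sincePlateau <- 0
      if (dropout > cfg$dropoutEnd + 1e-9) {
        dropout <- max(cfg$dropoutEnd, dropout - cfg$dropoutStep)
      } else {
        lr <- max(cfg$lrFloor, lr * cfg$lrDecay)
      }
    }
    if (sinceBest >= cfg$earlyStopPatience) break
  }
  model$params <- bestParams
  model$log <- log
  model$bestValAccuracy <- bestAcc
  model
}
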