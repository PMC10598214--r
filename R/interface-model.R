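## The per-position interface classifier: a four-layer fully connected
## head (three hidden layers + one-unit sigmoid output) applied
## independently at every residue position of a backend embedding,
## trained with masked, per-sequence-weighted binary cross entropy,
## minibatch Adam and early stopping on validation loss.

.BCE_EPS <- 1e-7

#' Masked, weighted binary cross entropy
#'
#' Computes `weight * mean over unmasked positions of
#' -(y log p + (1 - y) log(1 - p))`, with `p` clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithms. An all-`FALSE` mask yields 0.
#' Averaging (rather than summing) over positions keeps the loss
#' magnitude independent of sequence length; the per-sequence `weight`
#' multiplies the whole mean.
#'
#' @param p Predicted probabilities per position; must lie in \[0, 1\]
#'   before clamping.
#' @param y Binary labels per position.
#' @param mask Logical per position; `FALSE` positions are excluded.
#'   Default: all included.
#' @param weight Positive sequence weight (default 1).
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' bceLoss(0.5, 1)           # log(2)
#' bceLoss(0.5, 1, weight = 2)  # 2 * log(2)
bceLoss <- function(p, y, mask = NULL, weight = 1.0) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1] before clamping")
  stopifnot(length(p) == length(y), weight > 0)
  if (is.null(mask)) mask <- rep(TRUE, length(p))
  stopifnot(length(mask) == length(p))
  if (!any(mask)) return(0)
  pc <- pmin(pmax(p[mask], .BCE_EPS), 1 - .BCE_EPS)
  yy <- y[mask]
  weight * mean(-(yy * log(pc) + (1 - yy) * log(1 - pc)))
}

## ---------------------------------------------------------------------------
## Head: init / forward / backward
## ---------------------------------------------------------------------------

.activate <- function(Z, activation) {
  switch(activation,
         relu = pmax(Z, 0),
         gelu = Z * stats::pnorm(Z),
         stop("unknown activation: ", activation))
}

.activateGrad <- function(Z, activation) {
  switch(activation,
         relu = (Z > 0) * 1,
         gelu = stats::pnorm(Z) + Z * stats::dnorm(Z),
         stop("unknown activation: ", activation))
}

## He-style initialization of the four-layer head.
.initHead <- function(inputDim, hidden, seed) {
  stopifnot(length(hidden) == 3L, all(hidden >= 1L))
  dims <- c(inputDim, hidden, 1L)
  .withSeed(seed, {
    W <- lapply(1:4, function(l)
      matrix(stats::rnorm(dims[l] * dims[l + 1L], 0,
                          sqrt(2 / dims[l])), dims[l], dims[l + 1L]))
    b <- lapply(1:4, function(l) numeric(dims[l + 1L]))
    list(W = W, b = b)
  })
}

## Forward pass of the head on an n x d embedding matrix.
.headForward <- function(head, X, activation) {
  A <- X
  Z <- vector("list", 4L)
  As <- vector("list", 4L)
  for (l in 1:3) {
    Z[[l]] <- sweep(A %*% head$W[[l]], 2L, head$b[[l]], "+")
    A <- .activate(Z[[l]], activation)
    As[[l]] <- A
  }
  Z[[4L]] <- sweep(A %*% head$W[[4L]], 2L, head$b[[4L]], "+")
  p <- 1 / (1 + exp(-Z[[4L]][, 1L]))
  list(p = p, X = X, Z = Z, A = As)
}

## Backward pass: dz4 is dL/d(logit) per position (n-vector). Returns
## parameter gradients and dL/dX for backend fine-tuning.
.headBackward <- function(head, cache, dz4, activation) {
  gW <- vector("list", 4L)
  gb <- vector("list", 4L)
  dZ <- matrix(dz4, ncol = 1L)
  gW[[4L]] <- t(cache$A[[3L]]) %*% dZ
  gb[[4L]] <- colSums(dZ)
  dA <- dZ %*% t(head$W[[4L]])
  for (l in 3:1) {
    dZl <- dA * .activateGrad(cache$Z[[l]], activation)
    Ain <- if (l == 1L) cache$X else cache$A[[l - 1L]]
    gW[[l]] <- t(Ain) %*% dZl
    gb[[l]] <- colSums(dZl)
    dA <- dZl %*% t(head$W[[l]])
  }
  list(gW = gW, gb = gb, dX = dA)
}

## dL/d(logit) of the masked weighted mean BCE: (p - y) * w / n_unmasked
## on unmasked positions, 0 elsewhere.
.bceLogitGrad <- function(p, y, mask, weight) {
  g <- numeric(length(p))
  m <- sum(mask)
  if (m > 0) g[mask] <- weight * (p[mask] - y[mask]) / m
  g
}

## ---------------------------------------------------------------------------
## Adam
## ---------------------------------------------------------------------------

.adamInit <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

## params/grads are arbitrarily nested lists of numeric arrays.
.adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1 ^ tt)
    vh <- v / (1 - beta2 ^ tt)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = tt))
}

.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(Map(.addGrads, a, b))
  a + b
}

.scaleGrads <- function(a, s) {
  if (is.list(a)) return(lapply(a, .scaleGrads, s = s))
  a * s
}

## ---------------------------------------------------------------------------
## Early stopping
## ---------------------------------------------------------------------------

## Given a complete validation-loss schedule, return the epoch after which
## training with the given patience would stop, and the best epoch.
## Improvement is strict; the counter resets on every new best.
.stopSchedule <- function(valLosses, patience) {
  best <- Inf
  bestEpoch <- 0L
  since <- 0L
  for (e in seq_along(valLosses)) {
    if (valLosses[e] < best) {
      best <- valLosses[e]
      bestEpoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience)
        return(list(stopEpoch = e, bestEpoch = bestEpoch,
                    reason = "early_stopping"))
    }
  }
  list(stopEpoch = length(valLosses), bestEpoch = bestEpoch,
       reason = "max_epochs")
}

## ---------------------------------------------------------------------------
## Training
## ---------------------------------------------------------------------------

#' Default training configuration
#'
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize Sequences per gradient step (default 8).
#' @param maxEpochs Maximum epochs (default 30).
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (default 2). Training resumes from the
#'   best-validation-loss checkpoint.
#' @param seed Seed governing initialization and batch shuffling.
#' @return Named list of training settings.
#' @export
trainingConfig <- function(learningRate = 1e-3, batchSize = 8L,
                           maxEpochs = 30L, patience = 2L, seed = 1L) {
  stopifnot(learningRate > 0, batchSize >= 1L, maxEpochs >= 1L,
            patience >= 1L)
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       seed = as.integer(seed))
}

#' Train the per-position interface classifier
#'
#' Minibatch gradient descent (Adam) on masked, per-sequence-weighted
#' binary cross entropy. After each epoch the validation loss is
#' computed; training stops once it has failed to improve for
#' `patience` consecutive epochs (or at `maxEpochs`), and the returned
#' model is the best-validation-loss checkpoint. With a frozen backend
#' (`trainableLastK = 0`) embeddings are computed once and only the head
#' is updated; with `trainableLastK = k > 0` the final `k` backend blocks
#' are fine-tuned jointly with the head. Fully reproducible given the
#' seed in `trainConfig`.
#'
#' @param backend An [EmbeddingBackend-class].
#' @param trainSet,valSet Non-empty lists of [LabeledSequence-class] with
#'   disjoint sequence ids.
#' @param hidden Three hidden-layer sizes of the head (default
#'   `c(256, 128, 64)`).
#' @param activation `"relu"` (default) or `"gelu"`.
#' @param trainConfig A [trainingConfig()] list.
#' @return List with `model` (an [InterfaceModel-class]) and `report`
#'   (per-epoch `trainLoss` and `valLoss`, `bestEpoch`, `stopReason`).
#' @export
trainInterfaceModel <- function(backend, trainSet, valSet,
                                hidden = c(256L, 128L, 64L),
                                activation = c("relu", "gelu"),
                                trainConfig = trainingConfig()) {
  activation <- match.arg(activation)
  if (!length(trainSet) || !length(valSet))
    stop("train and validation sets must be non-empty")
  trainIds <- vapply(trainSet, sequenceId, character(1))
  valIds <- vapply(valSet, sequenceId, character(1))
  if (length(intersect(trainIds, valIds)))
    stop("train and validation ids must be disjoint: ",
         paste(intersect(trainIds, valIds), collapse = ", "))
  if (!any(vapply(trainSet, function(s) any(labelMask(s)), logical(1))))
    stop("training set is entirely masked")

  k <- trainableLastK(backend)
  tuneBackend <- k > 0L
  nb <- nBlocks(backend)
  firstTrainable <- if (tuneBackend) nb - k + 1L else NA_integer_

  ## Embedding cache. Frozen backend: final embeddings. Trainable: the
  ## output of the frozen block prefix (recomputed through the last k
  ## blocks each step).
  cacheFor <- function(set) {
    lapply(set, function(s) {
      if (!tuneBackend) return(embed(backend, residues(s)))
      codes <- .residueCodes(residues(s))
      X0 <- .ttInput(backend, codes)
      if (firstTrainable > 1L) {
        X <- X0
        for (b in seq_len(firstTrainable - 1L))
          X <- .blockForward(backend@blocks[[b]], X)$out
        X
      } else X0
    })
  }
  trainEmb <- cacheFor(trainSet)
  valEmb <- cacheFor(valSet)

  head <- .initHead(backendDim(backend), as.integer(hidden),
                    seed = trainConfig$seed)

  blocksT <- if (tuneBackend)
    backend@blocks[firstTrainable:nb] else list()
  params <- list(head = head, blocks = blocksT)
  adam <- .adamInit(params)

  forwardSeq <- function(prefix, withCache = FALSE) {
    if (!tuneBackend)
      return(list(X = prefix, ttCaches = NULL))
    X <- prefix
    caches <- vector("list", length(params$blocks))
    for (j in seq_along(params$blocks)) {
      step <- .blockForward(params$blocks[[j]], X, cache = withCache)
      if (withCache) caches[[j]] <- step
      X <- step$out
    }
    list(X = X, ttCaches = caches)
  }

  seqLoss <- function(s, prefix) {
    fw <- forwardSeq(prefix)
    hc <- .headForward(params$head, fw$X, activation)
    bceLoss(hc$p, siteLabels(s), labelMask(s), seqWeight(s))
  }

  valLoss <- function() {
    mean(vapply(seq_along(valSet), function(i)
      seqLoss(valSet[[i]], valEmb[[i]]), numeric(1)))
  }

  nTrain <- length(trainSet)
  best <- Inf
  bestParams <- params
  bestEpoch <- 0L
  since <- 0L
  stopReason <- "max_epochs"
  trainLosses <- numeric(0)
  valLosses <- numeric(0)

  epochOrders <- .withSeed(trainConfig$seed + 1L,
    lapply(seq_len(trainConfig$maxEpochs),
           function(e) sample.int(nTrain)))

  for (epoch in seq_len(trainConfig$maxEpochs)) {
    ord <- epochOrders[[epoch]]
    batchStarts <- seq(1L, nTrain, by = trainConfig$batchSize)
    epochLoss <- 0
    for (bs in batchStarts) {
      idx <- ord[bs:min(bs + trainConfig$batchSize - 1L, nTrain)]
      grads <- NULL
      batchLoss <- 0
      for (i in idx) {
        s <- trainSet[[i]]
        fw <- forwardSeq(trainEmb[[i]], withCache = tuneBackend)
        hc <- .headForward(params$head, fw$X, activation)
        y <- siteLabels(s); mask <- labelMask(s); w <- seqWeight(s)
        batchLoss <- batchLoss + bceLoss(hc$p, y, mask, w)
        dz4 <- .bceLogitGrad(hc$p, y, mask, w)
        hb <- .headBackward(params$head, hc, dz4, activation)
        g <- list(head = list(W = hb$gW, b = hb$gb), blocks = list())
        if (tuneBackend) {
          dX <- hb$dX
          gBlocks <- vector("list", length(params$blocks))
          for (j in rev(seq_along(params$blocks))) {
            bb <- .blockBackward(params$blocks[[j]], fw$ttCaches[[j]], dX)
            gBlocks[[j]] <- bb$grads
            dX <- bb$dXin
          }
          g$blocks <- gBlocks
        }
        grads <- .addGrads(grads, g)
      }
      grads <- .scaleGrads(grads, 1 / length(idx))
      upd <- .adamStep(params, grads, adam, trainConfig$learningRate)
      params <- upd$params
      adam <- upd$state
      epochLoss <- epochLoss + batchLoss
    }
    trainLosses <- c(trainLosses, epochLoss / nTrain)
    vl <- valLoss()
    valLosses <- c(valLosses, vl)
    if (vl < best) {
      best <- vl
      bestParams <- params
      bestEpoch <- epoch
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= trainConfig$patience) {
        stopReason <- "early_stopping"
        break
      }
    }
  }

  outBackend <- backend
  if (tuneBackend)
    outBackend@blocks[firstTrainable:nb] <- bestParams$blocks
  model <- new("InterfaceModel", backend = outBackend,
               head = bestParams$head,
               headConfig = list(hidden = as.integer(hidden),
                                 activation = activation),
               seed = trainConfig$seed)
  list(model = model,
       report = list(trainLoss = trainLosses, valLoss = valLosses,
                     bestEpoch = bestEpoch, stopReason = stopReason))
}

#' Predict per-position interface probabilities
#'
#' Runs the backend embedding and the trained head on one sequence,
#' returning the sigmoid-squashed per-position probability of belonging
#' to a protein-binding interface. Deterministic for a fixed model state.
#'
#' @param object An [InterfaceModel-class].
#' @param sequence A residue string, `AAString`, or named length-1
#'   `AAStringSet`.
#' @param sequenceId Optional id for the returned track.
#' @param ... Ignored.
#' @return A [PredictionTrack-class].
#' @export
setMethod("predict", "InterfaceModel",
          function(object, sequence, sequenceId = NULL, ...) {
  if (is.null(sequenceId))
    sequenceId <- .sequenceIdOf(sequence, "sequence")
  X <- embed(object@backend, sequence)
  hc <- .headForward(object@head, X, object@headConfig$activation)
  PredictionTrack(sequenceId, hc$p)
})

#' Predict tracks for a set of sequences
#'
#' @param model An [InterfaceModel-class].
#' @param sequences Named `AAStringSet` or named character vector.
#' @return Named list of [PredictionTrack-class].
#' @export
predictTracks <- function(model, sequences) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  stopifnot(!is.null(names(sequences)))
  out <- lapply(names(sequences), function(id)
    predict(model, sequences[[id]], sequenceId = id))
  stats::setNames(out, names(sequences))
}

#' Serialize / restore a trained model
#'
#' The checkpoint embeds the backend (with any fine-tuned parameters),
#' head weights, head configuration and training seed in a single file.
#'
#' @param model An [InterfaceModel-class].
#' @param path Checkpoint path.
#' @return `path` (save) / the model (load).
#' @export
saveModel <- function(model, path) {
  stopifnot(methods::is(model, "InterfaceModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(methods::is(model, "InterfaceModel"))
  model
}
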