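## Per-residue embedding backends.
##
## The classifier head is backend-agnostic: any object that maps a
## sequence of n residues to an n x d real matrix, deterministically for
## fixed parameters, can drive it. Two desk-scale built-ins are provided;
## a pretrained protein language model can be plugged in by subclassing
## EmbeddingBackend.

#' One-hot embedding with symmetric sequence context
#'
#' Encodes each residue as the concatenation of one-hot vectors (21
#' symbols: 20 amino acids + `X`) over a symmetric window of radius `r`
#' around it, so `dim = 21 * (2r + 1)`. Positions whose context extends
#' past a sequence boundary receive all-zero blocks there. The backend is
#' parameter-free, linear-time and fully deterministic, which makes it the
#' default for testing and for planted-motif recovery.
#'
#' @param radius Context radius `r` (default 7).
#' @return A `OneHotBackend` object.
#' @export
#' @examples
#' b <- oneHotBackend(0L)
#' dim(embed(b, "MK"))  # 2 x 21
oneHotBackend <- function(radius = 7L) {
  stopifnot(radius >= 0L)
  new("OneHotBackend", name = "onehot", radius = as.integer(radius))
}

#' Tiny self-attention encoder backend
#'
#' A small transformer encoder with seeded random initialization:
#' learned 21-symbol token embeddings plus fixed sinusoidal position
#' encodings, followed by `nBlocks` residual blocks of single-head
#' self-attention and a ReLU feed-forward layer (no layer
#' normalization). Its purpose is to exercise the fine-tuning contract —
#' marking the final `k` blocks trainable and updating them jointly with
#' the classifier head — at desk scale, not to approximate a pretrained
#' model's representations.
#'
#' @param embDim Embedding dimension (default 16).
#' @param numBlocks Number of encoder blocks (default 4).
#' @param seed Seed for parameter initialization.
#' @param trainableLastK How many final blocks start trainable (default 0,
#'   i.e. frozen).
#' @return A `TinyTransformerBackend` object.
#' @export
tinyTransformerBackend <- function(embDim = 16L, numBlocks = 4L, seed = 1L,
                                   trainableLastK = 0L) {
  stopifnot(embDim >= 2L, numBlocks >= 1L)
  d <- as.integer(embDim)
  init <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, 0, scale),
                                         nr, nc)
  params <- .withSeed(seed, {
    tok <- init(21L, d, 1 / sqrt(d))
    blocks <- lapply(seq_len(numBlocks), function(b) {
      list(Wq = init(d, d, 1 / sqrt(d)), Wk = init(d, d, 1 / sqrt(d)),
           Wv = init(d, d, 1 / sqrt(d)), Wo = init(d, d, 1 / sqrt(d)),
           W1 = init(d, 2L * d, 1 / sqrt(d)), b1 = numeric(2L * d),
           W2 = init(2L * d, d, 1 / sqrt(2 * d)), b2 = numeric(d))
    })
    list(tok = tok, blocks = blocks)
  })
  new("TinyTransformerBackend", name = "tinytransformer", embDim = d,
      blocks = params$blocks, tokenEmbedding = params$tok,
      trainableLastK = as.integer(trainableLastK), seed = as.integer(seed))
}

#' @rdname oneHotBackend
#' @param backend A backend object.
#' @export
setMethod("backendDim", "OneHotBackend", function(backend)
  21L * (2L * backend@radius + 1L))

#' @rdname tinyTransformerBackend
#' @param backend A backend object.
#' @export
setMethod("backendDim", "TinyTransformerBackend", function(backend)
  backend@embDim)

setMethod("nBlocks", "OneHotBackend", function(backend) 0L)
setMethod("nBlocks", "TinyTransformerBackend", function(backend)
  length(backend@blocks))

setMethod("trainableLastK", "OneHotBackend", function(backend) 0L)
setMethod("trainableLastK", "TinyTransformerBackend", function(backend)
  backend@trainableLastK)

setMethod("setTrainable", "OneHotBackend", function(backend, lastK) {
  if (lastK > 0L)
    stop("the one-hot backend has no trainable blocks (lastK must be 0)")
  backend
})

setMethod("setTrainable", "TinyTransformerBackend",
          function(backend, lastK) {
  lastK <- as.integer(lastK)
  if (lastK < 0L || lastK > length(backend@blocks))
    stop("lastK must lie in [0, ", length(backend@blocks), "]")
  backend@trainableLastK <- lastK
  backend
})

## residue string -> integer codes 1..21
.residueCodes <- function(res) {
  codes <- match(strsplit(res, "", fixed = TRUE)[[1L]], .AA21)
  if (anyNA(codes))
    stop("sequence contains symbols outside the amino-acid alphabet + 'X'")
  codes
}

setMethod("embed", "OneHotBackend", function(backend, sequence, ...) {
  res <- .asResidues(sequence)
  codes <- .residueCodes(res)
  n <- length(codes)
  r <- backend@radius
  M <- matrix(0, n, 21L * (2L * r + 1L))
  for (o in -r:r) {
    block <- (o + r) * 21L
    i <- seq_len(n)
    src <- i + o
    ok <- src >= 1L & src <= n
    M[cbind(i[ok], block + codes[src[ok]])] <- 1
  }
  M
})

## fixed sinusoidal position encodings, n x d
.posEncoding <- function(n, d) {
  pos <- seq_len(n) - 1L
  P <- matrix(0, n, d)
  for (j in seq_len(d)) {
    freq <- 1 / (10000 ^ ((2 * ((j - 1) %/% 2)) / d))
    P[, j] <- if (j %% 2L == 1L) sin(pos * freq) else cos(pos * freq)
  }
  P
}

## One transformer block forward. Returns output plus (optionally) the
## intermediates needed for backprop.
.blockForward <- function(blk, X, cache = FALSE) {
  d <- ncol(X)
  Q <- X %*% blk$Wq
  K <- X %*% blk$Wk
  V <- X %*% blk$Wv
  S <- (Q %*% t(K)) / sqrt(d)
  S <- sweep(S, 1L, apply(S, 1L, max)) # row-wise stabilization
  A <- exp(S)
  A <- A / rowSums(A)
  H <- A %*% V
  X1 <- X + H %*% blk$Wo
  Z <- sweep(X1 %*% blk$W1, 2L, blk$b1, "+")
  R <- pmax(Z, 0)
  Xout <- X1 + sweep(R %*% blk$W2, 2L, blk$b2, "+")
  if (!cache) return(list(out = Xout))
  list(out = Xout, Xin = X, Q = Q, K = K, V = V, A = A, H = H, X1 = X1,
       Z = Z, R = R)
}

## Backward through one block: given dL/dXout and the forward cache,
## return dL/dXin and the parameter gradients.
.blockBackward <- function(blk, cache, dOut) {
  d <- ncol(cache$Xin)
  ## feed-forward
  dF <- dOut
  gW2 <- t(cache$R) %*% dF
  gb2 <- colSums(dF)
  dR <- dF %*% t(blk$W2)
  dZ <- dR * (cache$Z > 0)
  gW1 <- t(cache$X1) %*% dZ
  gb1 <- colSums(dZ)
  dX1 <- dOut + dZ %*% t(blk$W1)
  ## attention
  dG <- dX1
  gWo <- t(cache$H) %*% dG
  dH <- dG %*% t(blk$Wo)
  dA <- dH %*% t(cache$V)
  dV <- t(cache$A) %*% dH
  rowdot <- rowSums(dA * cache$A)
  dS <- cache$A * (dA - rowdot)
  dQ <- (dS %*% cache$K) / sqrt(d)
  dK <- (t(dS) %*% cache$Q) / sqrt(d)
  gWq <- t(cache$Xin) %*% dQ
  gWk <- t(cache$Xin) %*% dK
  gWv <- t(cache$Xin) %*% dV
  dXin <- dX1 + dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) + dV %*% t(blk$Wv)
  list(dXin = dXin,
       grads = list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo,
                    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

## Full transformer forward. fromBlock allows starting from a cached
## intermediate (the output of the frozen prefix); caches are kept only
## from that block on.
.ttForward <- function(backend, X0, fromBlock = 1L, cache = FALSE) {
  X <- X0
  caches <- vector("list", length(backend@blocks))
  for (b in seq(from = fromBlock, length.out =
                  length(backend@blocks) - fromBlock + 1L)) {
    step <- .blockForward(backend@blocks[[b]], X, cache = cache)
    if (cache) caches[[b]] <- step
    X <- step$out
  }
  list(out = X, caches = caches)
}

.ttInput <- function(backend, codes) {
  n <- length(codes)
  backend@tokenEmbedding[codes, , drop = FALSE] +
    .posEncoding(n, backend@embDim)
}

setMethod("embed", "TinyTransformerBackend",
          function(backend, sequence, ...) {
  res <- .asResidues(sequence)
  codes <- .residueCodes(res)
  .ttForward(backend, .ttInput(backend, codes))$out
})
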