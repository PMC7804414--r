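## Low-level CNN layer operations.
##
## Activations are 4-D arrays laid out (H, W, N, C) — R is column-major, so
## with channels last a per-channel matrix view (H*W*N x C) is a plain
## `dim<-` with no copy and channel concatenation is `c(a, b)`. The heavy
## kernels (3x3 convolution forward/backward, batch-norm loops, 2x2 pooling)
## live in src/conv_ops.cpp; convolution weights are (9*Cin x Cout) matrices.
## The transposed convolution reuses the ordinary convolution after
## zero-stuffed upsampling, which is the exact adjoint of strided pooling
## geometry.

conv3x3_forward <- function(X, W, b) {
  .conv3x3_fwd_cpp(X, dim(X), W, b)
}

conv3x3_backward <- function(dY, X, W) {
  .conv3x3_bwd_cpp(dY, X, dim(X), W)
}

conv1x1_forward <- function(X, W, b) {
  d <- dim(X)
  m <- X; dim(m) <- c(prod(d[1:3]), d[4])
  Y <- m %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(d[1], d[2], d[3], length(b))
  Y
}

conv1x1_backward <- function(dY, X, W) {
  d <- dim(X)
  m <- X; dim(m) <- c(prod(d[1:3]), d[4])
  dYm <- dY; dim(dYm) <- c(prod(d[1:3]), dim(dY)[4])
  dX <- tcrossprod(dYm, W)
  dim(dX) <- d
  list(dX = dX, dW = crossprod(m, dYm), db = colSums(dYm))
}

## Batch normalisation over (H, W, N) per channel. Population statistics are
## tracked with exponential smoothing for inference.
bn_forward <- function(X, gamma, beta, training, rmean, rvar,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(X); C <- d[4]; n <- prod(d[1:3])
  if (training) {
    st <- .bn_stats_cpp(X, n, C)
    mu <- st$mean; v <- st$var
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean; v <- rvar
  }
  istd <- 1 / sqrt(v + eps)
  ap <- .bn_apply_cpp(X, n, C, mu, istd, gamma, beta)
  Y <- ap$Y
  dim(Y) <- d
  list(Y = Y, xhat = ap$xhat, istd = istd, rmean = rmean, rvar = rvar)
}

bn_backward <- function(dY, cache, gamma) {
  d <- dim(dY); C <- d[4]; n <- prod(d[1:3])
  bk <- .bn_bwd_cpp(dY, cache$xhat, n, C, cache$istd, gamma)
  dX <- bk$dX
  dim(dX) <- d
  list(dX = dX, dgamma = bk$dgamma, dbeta = bk$dbeta)
}

relu_forward <- function(X) X * (X > 0)
relu_backward <- function(dY, Y) dY * (Y > 0)

maxpool_forward <- function(X) {
  mp <- .maxpool_fwd_cpp(X, dim(X))
  list(Y = mp$Y, arg = mp$arg, dims = dim(X))
}

maxpool_backward <- function(dY, cache) {
  .maxpool_bwd_cpp(dY, cache$arg, cache$dims)
}

## Zero-stuffed 2x upsampling: a stride-2 transposed 3x3 convolution equals
## zero-stuffing followed by an ordinary (stride-1, same-padding) 3x3
## convolution, so the transposed layer reuses conv3x3_* wholesale.
zerostuff_forward <- function(X) {
  d <- dim(X)
  Z <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  Z[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , ] <- X
  Z
}

zerostuff_backward <- function(dZ) {
  dZ[seq(1L, dim(dZ)[1], 2L), seq(1L, dim(dZ)[2], 2L), , , drop = FALSE]
}

dropout_forward <- function(X, rate) {
  mask <- (runif(length(X)) >= rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(Y = X * mask, mask = mask)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Combined binary cross-entropy + Dice loss
#'
#' `bce_weight * BCE(pred, target) + dice_weight * (1 - Dice(pred, target))`
#' with `Dice = (2 * sum(pred*target) + eps) / (sum(pred) + sum(target) + eps)`.
#' BCE is averaged over pixels; predictions are clamped away from 0 and 1 for
#' numerical stability.
#'
#' @param pred predicted probabilities in (0, 1), any shape.
#' @param target binary target of the same shape.
#' @param bce_weight,dice_weight weights of the two terms (default 1 each).
#' @param eps Dice smoothing constant.
#' @return scalar loss, always >= 0.
#' @export
bce_dice_loss <- function(pred, target, bce_weight = 1, dice_weight = 1,
                          eps = 1e-6) {
  if (!identical(dim(pred), dim(target)) &&
      !(is.null(dim(pred)) && length(pred) == length(target)))
    stop("pred and target shapes differ")
  p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dice <- (2 * sum(p * target) + eps) / (sum(p) + sum(target) + eps)
  bce_weight * bce + dice_weight * (1 - dice)
}

## Loss and gradient w.r.t. logits (pre-sigmoid), used in training.
bce_dice_grad <- function(logits, target, bce_weight = 1, dice_weight = 1,
                          eps = 1e-6) {
  p <- sigmoid(logits)
  n <- length(p)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  nu <- 2 * sum(p * target) + eps
  de <- sum(p) + sum(target) + eps
  loss <- bce_weight * bce + dice_weight * (1 - nu / de)
  dp_dice <- (nu - 2 * target * de) / de^2 # d(1 - Dice)/dp
  dlogits <- bce_weight * (p - target) / n + dice_weight * dp_dice * p * (1 - p)
  list(loss = loss, dlogits = dlogits)
}
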